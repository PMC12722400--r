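sig_from_cells <- function(a, b, c, d, pt = "x") {
  ror(contingency_table(a, b, c, d, pt = pt))
}

test_that("age conversion honours the unit codes and flags unknown ones", {
  got <- convert_age_years(c(46, 552, 5, 104.28, 730.5, 30),
                           c("YR", "MON", "DEC", "WK", "DY", "XX"))
  expect_equal(got[1:5], c(46, 46, 50, 2, 2), tolerance = 1e-6)
  expect_true(is.na(got[6]))
  expect_equal(attr(got, "n_unknown_unit"), 1)
  # blank unit treated as years
  expect_equal(convert_age_years(33, NA)[1], 33)
})

test_that("age strata split at the 64/65 boundary and missing strata drop out", {
  b <- tiny_bundle()
  b$demo$age <- c(64, 65, 17, 18, NA, 40, 40, 40, 40, 40)
  s <- stratify_reports(b, "age_group")
  expect_equal(s$stratum[1:4], c("adult", "older_adult", NA, "adult"))
  expect_true(is.na(s$stratum[5]))
  # non-year units excluded when age_years_only is on
  b$demo$age_unit[6] <- "MON"
  s2 <- stratify_reports(b, "age_group", age_years_only = TRUE)
  expect_true(is.na(s2$stratum[6]))
  s3 <- stratify_reports(b, "age_group", age_years_only = FALSE)
  expect_true(is.na(s3$stratum[6]))  # 40 months is under 18 years
  # sex strata keep F/M only
  b$demo$sex[1] <- NA
  ss <- stratify_reports(b, "sex")
  expect_true(is.na(ss$stratum[1]))
  expect_setequal(unique(ss$stratum[-1]), c("F", "M"))
})

test_that("relative ROR reproduces the published sedation sex contrast", {
  rel <- relative_ror(135.82, 104.46)
  expect_equal(round_half_up(rel$rel_ror, 2), 1.30)
})

test_that("identical strata give relative ROR 1 and no difference", {
  r <- sig_from_cells(40, 160, 100, 1900)
  rel <- relative_ror(r, r)
  expect_equal(rel$rel_ror, 1)
  expect_equal(rel$classification, "no_difference")
})

test_that("swapping strata inverts the relative ROR and mirrors its CI", {
  r1 <- sig_from_cells(40, 160, 100, 1900)
  r2 <- sig_from_cells(25, 175, 120, 1880)
  fwd <- relative_ror(r1, r2)
  rev <- relative_ror(r2, r1)
  expect_equal(rev$rel_ror, 1 / fwd$rel_ror)
  expect_equal(rev$rel_ci_low, 1 / fwd$rel_ci_high)
  expect_equal(rev$rel_ci_high, 1 / fwd$rel_ci_low)
  # the CI contains the point estimate and has the combined log-width
  expect_true(fwd$rel_ci_low <= fwd$rel_ror && fwd$rel_ror <= fwd$rel_ci_high)
  z <- qnorm(0.975)
  w1 <- log(r1$ci_high) - log(r1$ror)
  w2 <- log(r2$ci_high) - log(r2$ror)
  expect_equal(log(fwd$rel_ci_high) - log(fwd$rel_ror),
               sqrt(w1^2 + w2^2), tolerance = 1e-10)
  # below the report floor the comparison is not evaluable
  small <- sig_from_cells(4, 16, 10, 190)
  expect_equal(relative_ror(small, r2)$classification, "not_evaluable")
})

test_that("relative-ROR CI matches a parametric log-normal resampling oracle", {
  set.seed(7)
  for (cells in list(c(40, 160, 100, 1900, 25, 175, 120, 1880),
                     c(15, 85, 30, 970, 22, 78, 45, 955))) {
    r1 <- sig_from_cells(cells[1], cells[2], cells[3], cells[4])
    r2 <- sig_from_cells(cells[5], cells[6], cells[7], cells[8])
    rel <- relative_ror(r1, r2)
    se1 <- sqrt(sum(1 / cells[1:4])); se2 <- sqrt(sum(1 / cells[5:8]))
    draws <- exp(rnorm(1e5, log(r1$ror), se1)) /
      exp(rnorm(1e5, log(r2$ror), se2))
    q <- quantile(draws, c(0.025, 0.975))
    expect_equal(rel$rel_ci_low, unname(q[1]), tolerance = 0.02)
    expect_equal(rel$rel_ci_high, unname(q[2]), tolerance = 0.02)
  }
})

test_that("the dual criterion classifies strata and records exclusivity", {
  b_cells <- c(30, 370, 100, 9900)  # a clear signal, ror ~ 8
  flat <- c(10, 390, 250, 9750)     # ror ~ 1
  sim_tbl <- function(c1, c2) {
    s1 <- ror_cells <- sig_from_cells(c1[1], c1[2], c1[3], c1[4])
    s2 <- sig_from_cells(c2[1], c2[2], c2[3], c2[4])
    relative_ror(s1, s2)
  }
  cmp <- sim_tbl(b_cells, flat)
  expect_equal(cmp$classification, "stratum1_higher")
  # both strata signalling with a relative CI spanning 1: no difference
  cmp2 <- sim_tbl(b_cells, b_cells + c(2, -2, 0, 0))
  expect_equal(cmp2$classification, "no_difference")
})

test_that("a planted sex effect is classified female-higher in most replicates", {
  set.seed(15)
  n_rep <- 200
  n_case <- 500; n_non <- 10000; p0 <- 0.08
  or_f <- 4
  pf <- or_f * p0 / (1 - p0) / (1 + or_f * p0 / (1 - p0))
  hits <- vapply(seq_len(n_rep), function(i) {
    a1 <- stats::rbinom(1, n_case, pf); c1 <- stats::rbinom(1, n_non, p0)
    a2 <- stats::rbinom(1, n_case, p0); c2 <- stats::rbinom(1, n_non, p0)
    cmp <- relative_ror(
      sig_from_cells(a1, n_case - a1, c1, n_non - c1),
      sig_from_cells(a2, n_case - a2, c2, n_non - c2)
    )
    cmp$classification == "stratum1_higher"
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("with no stratum effect the dual criterion rarely fires", {
  set.seed(25)
  n_rep <- 500
  n_case <- 300; n_non <- 8000; p0 <- 0.1
  or <- 2  # both strata share a genuine signal, no difference between them
  p1 <- or * p0 / (1 - p0) / (1 + or * p0 / (1 - p0))
  diff_rate <- mean(vapply(seq_len(n_rep), function(i) {
    a1 <- stats::rbinom(1, n_case, p1); c1 <- stats::rbinom(1, n_non, p0)
    a2 <- stats::rbinom(1, n_case, p1); c2 <- stats::rbinom(1, n_non, p0)
    cmp <- relative_ror(
      sig_from_cells(a1, n_case - a1, c1, n_non - c1),
      sig_from_cells(a2, n_case - a2, c2, n_non - c2)
    )
    cmp$classification %in% c("stratum1_higher", "stratum2_higher")
  }, logical(1)))
  expect_lt(diff_rate, 0.10)
})

test_that("stratified analysis on a generated bundle matches per-stratum recounts", {
  cfg <- sim_config(
    n_reports = 15000, seed = 61,
    planted_signals = tibble::tibble(drug = "esketamine", pt = "Nausea",
                                     odds_multiplier = 4),
    sex_effects = tibble::tibble(pt = "Nausea",
                                 female_odds_multiplier = 3),
    planted_interactions = NULL,
    dup_rates = c(caseid = 0, fieldmatch = 0), deleted_rate = 0
  )
  sim <- simulate_reports(cfg)
  fl <- flag_cases(sim$bundle, tiny_cd())
  out <- stratified_analysis(sim$bundle, fl, "sex")
  expect_true(all(out$a1 >= 5 & out$a2 >= 5))
  # stratum counts equal a brute-force recount for the planted term
  sm <- stratify_reports(sim$bundle, "sex")
  for (s in c("F", "M")) {
    pids <- sm$primaryid[!is.na(sm$stratum) & sm$stratum == s]
    sub <- sim$bundle
    for (nm in c("demo", "drug", "reac", "outc", "ther", "indi")) {
      sub[[nm]] <- sub[[nm]][sub[[nm]]$primaryid %in% pids, ]
    }
    o <- oracle_contingency(sub, fl[fl$primaryid %in% pids, ], "Nausea")
    col <- if (s == "F") "a1" else "a2"
    expect_equal(out[[col]][out$pt == "Nausea"], unname(o["a"]))
  }
  # the planted female modifier shows up in the orientation of the estimate
  expect_gt(out$rel_ror[out$pt == "Nausea"], 1)
  fd <- forest_data(out)
  expect_true(all(fd$rel_ror >= 1))
  expect_true(all(fd$ci_low <= fd$rel_ror & fd$rel_ror <= fd$ci_high))
})
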