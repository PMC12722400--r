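make_demo <- function(...) {
  rows <- list(...)
  demo <- dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(primaryid = r[[1]], caseid = r[[2]], fda_dt = r[[3]])
  }))
  demo$event_dt <- NA_character_; demo$sex <- "F"; demo$age <- 30
  demo$age_unit <- "YR"; demo$weight <- NA_real_; demo$country_code <- "US"
  demo$reporter_qualification <- "MD"; demo$report_year <- "2023"
  empty <- tibble::tibble(primaryid = character(), drug_seq = character(),
                          role_code = character(), drug_name = character(),
                          ingredient = character())
  report_bundle(demo, empty,
                tibble::tibble(primaryid = character(), pt = character()),
                tibble::tibble(primaryid = character(),
                               outcome_code = character()),
                empty[, c("primaryid", "drug_seq")] |>
                  dplyr::mutate(start_dt = character(0),
                                end_dt = character(0)),
                empty[, c("primaryid", "drug_seq")] |>
                  dplyr::mutate(indication_pt = character(0)))
}

test_that("caseid dedup keeps the most recent FDA date, ties to highest primaryid", {
  b <- make_demo(list("10", "7", "20230101"), list("9", "7", "20230301"))
  expect_equal(dedup_caseid(b)$demo$primaryid, "9")
  b2 <- make_demo(list("10", "7", "20230101"), list("12", "7", "20230101"))
  expect_equal(dedup_caseid(b2)$demo$primaryid, "12")
  expect_equal(attr(dedup_caseid(b2), "n_removed"), 1)
})

test_that("caseid dedup equals a group-by/argmax oracle on bundles with planted duplicates", {
  sim <- simulate_reports(sim_config(n_reports = 2000, seed = 5,
                                     dup_rates = c(caseid = 0.1,
                                                   fieldmatch = 0)))
  got <- dedup_caseid(sim$bundle)
  expect_setequal(got$demo$primaryid, oracle_dedup_caseid(sim$bundle$demo))
  # every injected duplicate pair collapsed: recall 1.0
  pairs <- sim$truth$dup_caseid
  both <- (pairs$original %in% got$demo$primaryid) +
    (pairs$clone %in% got$demo$primaryid)
  expect_true(all(both == 1))
  # idempotence and monotonicity
  again <- dedup_caseid(got)
  expect_equal(again$demo$primaryid, got$demo$primaryid)
  expect_lte(nrow(got$demo), nrow(sim$bundle$demo))
})

test_that("field-match dedup collapses clones and keeps the highest primaryid", {
  b <- tiny_bundle()
  # clone report 1 as primaryid 20 with a different caseid
  clone <- function(bundle, src, new_pid, new_caseid) {
    for (nm in c("drug", "reac", "outc", "ther", "indi")) {
      t <- bundle[[nm]][bundle[[nm]]$primaryid == src, ]
      t$primaryid <- new_pid
      bundle[[nm]] <- dplyr::bind_rows(bundle[[nm]], t)
    }
    d <- bundle$demo[bundle$demo$primaryid == src, ]
    d$primaryid <- new_pid; d$caseid <- new_caseid
    bundle$demo <- dplyr::bind_rows(bundle$demo, d)
    bundle
  }
  b2 <- clone(b, "1", "20", "999")
  got <- dedup_fieldmatch(b2)
  expect_false("1" %in% got$demo$primaryid)
  expect_true("20" %in% got$demo$primaryid)
  expect_equal(attr(got, "n_removed"), 1)
  # a single differing reaction term breaks the key: both kept
  b3 <- clone(b, "1", "21", "998")
  b3$reac$pt[b3$reac$primaryid == "21" & b3$reac$pt == "Nausea"] <- "Tremor"
  expect_equal(nrow(dedup_fieldmatch(b3)$demo), nrow(b3$demo))
})

test_that("field-match dedup equals the brute-force key-grouping oracle", {
  sim <- simulate_reports(sim_config(n_reports = 600, seed = 9,
                                     dup_rates = c(caseid = 0,
                                                   fieldmatch = 0.08)))
  b <- sim$bundle
  keys <- oracle_fieldmatch_keys(b)
  expected <- unlist(lapply(split(b$demo$primaryid, keys), function(p) {
    p[which.max(as.numeric(p))]
  }), use.names = FALSE)
  got <- dedup_fieldmatch(b)
  expect_setequal(got$demo$primaryid, expected)
  expect_equal(dedup_fieldmatch(got)$demo$primaryid, got$demo$primaryid)
})

test_that("deleted-case removal is an exact set difference", {
  b <- make_demo(list("1", "1", "20230101"), list("2", "2", "20230101"),
                 list("3", "3", "20230101"))
  got <- remove_deleted(b, deleted = "2")
  expect_setequal(got$demo$caseid, c("1", "3"))
  expect_equal(attr(got, "n_removed"), 1)
  unchanged <- remove_deleted(b, deleted = c("98", "99"))
  expect_equal(unchanged$demo, b$demo)
})

test_that("case flagging follows the role and indication rules", {
  b <- tiny_bundle()
  fl <- flag_cases(b, tiny_cd())
  # PS with psychiatric indication and SS both qualify
  expect_true(all(fl$is_case[fl$primaryid %in% c("1", "2", "3")]))
  # concomitant-only target is a non-case
  expect_false(fl$is_case[fl$primaryid == "4"])
  # anaesthetic indication excludes an otherwise eligible report
  expect_false(fl$is_case[fl$primaryid == "5"])
  expect_false(any(fl$is_case[fl$primaryid %in% as.character(6:10)]))
  expect_equal(attr(fl, "n_excluded_role"), 1)
  expect_equal(attr(fl, "n_excluded_indication"), 1)
  # partition is exhaustive
  expect_equal(sum(fl$is_case) + sum(!fl$is_case), nrow(b$demo))
  # absent target warns, zero cases
  cd2 <- case_definition("nonexistium")
  expect_warning(fl2 <- flag_cases(b, cd2), "absent")
  expect_equal(sum(fl2$is_case), 0)
})

test_that("contingency tables equal a brute-force membership recount", {
  b <- tiny_bundle()
  fl <- flag_cases(b, tiny_cd())
  for (pt in c("Vertigo", "Nausea", "Sedation", "Headache")) {
    ct <- build_contingency(b, fl, pt)
    o <- oracle_contingency(b, fl, pt)
    expect_equal(c(a = ct$a, b = ct$b, c = ct$c, d = ct$d), o, label = pt)
  }
  # unknown term gives the degenerate table
  ct0 <- build_contingency(b, fl, "Absentia")
  expect_equal(c(ct0$a, ct0$c), c(0, 0))
  expect_equal(ct0$b, sum(fl$is_case))
  expect_equal(ct0$d, sum(!fl$is_case))
})

test_that("contingency recount holds on a random synthetic bundle across all terms", {
  sim <- simulate_reports(sim_config(n_reports = 400, seed = 21,
                                     dup_rates = c(caseid = 0,
                                                   fieldmatch = 0),
                                     deleted_rate = 0))
  b <- sim$bundle
  fl <- flag_cases(b, tiny_cd())
  all_t <- build_contingency_all(b, fl)
  expect_gt(nrow(all_t), 5)
  for (i in seq_len(nrow(all_t))) {
    o <- oracle_contingency(b, fl, all_t$pt[i])
    expect_equal(c(a = all_t$a[i], b = all_t$b[i], c = all_t$c[i],
                   d = all_t$d[i]), o, label = all_t$pt[i])
  }
  # a + b equals the case count for every term
  expect_true(all(all_t$a + all_t$b == sum(fl$is_case)))
  # duplicated term on one report counts once
  b$reac <- dplyr::bind_rows(b$reac, b$reac[1, ])
  ct <- build_contingency(b, fl, b$reac$pt[1])
  o <- oracle_contingency(b, fl, b$reac$pt[1])
  expect_equal(ct$a + ct$c, unname(o["a"] + o["c"]))
})
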