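test_that("tiny-universe DDI counts equal hand enumeration", {
  b <- tiny_bundle()
  fl <- flag_cases(b, tiny_cd())
  # cases: 1, 2, 3; risperidone in PS/SS/I role on reports 1, 3, 6
  ct <- ddi_counts(b, fl, "risperidone", "Vertigo", universe = "all_reports")
  expect_equal(ct$n_AB1, 1)       # report 1 (case, risperidone, vertigo)
  expect_equal(ct$n_A1, 1)        # report 2 (case, no risperidone, vertigo)
  expect_equal(ct$n_AB_plus, 2)   # reports 1, 3
  expect_equal(ct$n_B_plus, 1)    # report 6 (role C on 8 does not count)
  expect_equal(ct$n_plusplus, 10)
  expect_equal(c(ct$n11, ct$N11), c(1, 2))
  expect_equal(c(ct$n10, ct$N10), c(1, 1))
  expect_equal(c(ct$n01, ct$N01), c(1, 1))
  expect_equal(c(ct$n00, ct$N00), c(2, 6))
  # case-report universe zeroes the B-without-A margin
  ctc <- ddi_counts(b, fl, "risperidone", "Vertigo")
  expect_equal(ctc$n_B_plus, 0)
  expect_equal(ctc$n_plusplus, 3)
  # absent drug B gives the degenerate counts
  ct0 <- ddi_counts(b, fl, "absentol", "Vertigo")
  expect_equal(c(ct0$n_AB1, ct0$n_AB_plus, ct0$n_B_plus), c(0, 0, 0))
})

test_that("lift and conviction follow their printed formulas", {
  # hand-arithmetic check: confidence 4/20, support 10/100
  ct <- ddi_count_set(n_AB1 = 4, n_A1 = 6, n_AB_plus = 12, n_B_plus = 8,
                      n_plusplus = 100, n11 = 4, N11 = 12, n10 = 6,
                      N10 = 20, n01 = 2, N01 = 8, n00 = 5, N00 = 60)
  expect_equal(ddi_lift(ct), (4 / 20) / (10 / 100))
  expect_equal(ddi_conviction(ct), (1 - 0.1) / (1 - 0.2))
  # exact independence: confidence equals support
  ind <- ddi_count_set(n_AB1 = 2, n_A1 = 8, n_AB_plus = 10, n_B_plus = 10,
                       n_plusplus = 100, n11 = 2, N11 = 10, n10 = 8,
                       N10 = 40, n01 = 2, N01 = 10, n00 = 8, N00 = 40)
  expect_equal(ddi_lift(ind), 1)
  expect_equal(ddi_conviction(ind), 1)
  # confidence of 1 yields the infinity sentinel
  conf1 <- ddi_count_set(n_AB1 = 5, n_A1 = 1, n_AB_plus = 5, n_B_plus = 0,
                         n_plusplus = 50, n11 = 5, N11 = 5, n10 = 1,
                         N10 = 10, n01 = 0, N01 = 5, n00 = 1, N00 = 30)
  expect_identical(ddi_conviction(conf1), Inf)
})

test_that("additive and multiplicative interaction scores match their formulas", {
  cells <- function(p11, p10, p01, p00, N = 1000) {
    ddi_count_set(n_AB1 = p11 * N, n_A1 = p10 * N,
                  n_AB_plus = N, n_B_plus = N, n_plusplus = 4 * N,
                  n11 = p11 * N, N11 = N, n10 = p10 * N, N10 = N,
                  n01 = p01 * N, N01 = N, n00 = p00 * N, N00 = N)
  }
  expect_equal(additive_interaction(cells(0.4, 0.2, 0.15, 0.05)), 0.10)
  expect_equal(multiplicative_interaction(cells(0.4, 0.2, 0.1, 0.05)), 1)
  # exact additivity and multiplicativity boundaries
  expect_equal(additive_interaction(cells(0.30, 0.20, 0.15, 0.05)), 0)
  expect_equal(multiplicative_interaction(cells(0.32, 0.16, 0.10, 0.05)), 1)
  # empty exposure cell is not evaluable
  empty <- ddi_count_set(n_AB1 = 0, n_A1 = 0, n_AB_plus = 0, n_B_plus = 0,
                         n_plusplus = 10, n11 = 0, N11 = 0, n10 = 1,
                         N10 = 5, n01 = 1, N01 = 5, n00 = 1, N00 = 5)
  expect_true(is.na(additive_interaction(empty)))
  expect_true(is.na(multiplicative_interaction(empty)))
})

test_that("the combination risk ratio hits its constructed boundaries", {
  # A and B each double the AE rate; the combination quadruples it. With
  # exposure cells small against the unexposed pool, each single-drug PRR
  # approaches its risk ratio of 2 and the combination PRR approaches 4,
  # so CRR lands at its signal boundary of 2.
  N <- 1000; N00 <- 50000
  cells <- ddi_count_set(
    n_AB1 = 0.4 * N, n_A1 = 0.2 * N, n_AB_plus = N, n_B_plus = N,
    n_plusplus = 2 * N + N00,
    n11 = 0.4 * N, N11 = N, n10 = 0.2 * N, N10 = N,
    n01 = 0.2 * N, N01 = N, n00 = 0.1 * N00, N00 = N00
  )
  crr <- combination_risk_ratio(cells)
  expect_equal(crr, 2, tolerance = 0.1)
  # B inert, no interaction: CRR near 1
  inert <- ddi_count_set(
    n_AB1 = 0.2 * N, n_A1 = 0.2 * N, n_AB_plus = N, n_B_plus = N,
    n_plusplus = 2 * N + N00,
    n11 = 0.2 * N, N11 = N, n10 = 0.2 * N, N10 = N,
    n01 = 0.1 * N, N01 = N, n00 = 0.1 * N00, N00 = N00
  )
  expect_equal(combination_risk_ratio(inert), 1, tolerance = 0.1)
})

test_that("all five scores equal brute-force enumeration on small universes", {
  for (seed in c(3, 14, 27)) {
    b <- random_small_bundle(n = 40, seed = seed)
    fl <- flag_cases(b, tiny_cd())
    for (u in c("case_reports", "all_reports")) {
      got <- ddi_counts(b, fl, "drugb", "Vertigo", universe = u)
      want <- oracle_ddi_counts(b, fl, "drugb", "Vertigo", universe = u)
      expect_equal(unclass(got), unclass(want),
                   label = sprintf("seed %d %s", seed, u))
      for (f in list(ddi_lift, ddi_conviction, additive_interaction,
                     multiplicative_interaction, combination_risk_ratio)) {
        expect_equal(f(got), f(want))
      }
    }
  }
})

test_that("triple selection honours signal status, exclusions, roles and the co-case floor", {
  b <- tiny_bundle()
  fl <- flag_cases(b, tiny_cd())
  signals <- tibble::tibble(
    pt = c("Vertigo", "Suicidal ideation", "Sedation"),
    is_signal = c(TRUE, TRUE, FALSE)
  )
  tr <- select_eligible_triples(b, fl, signals, tiny_cd(), min_co_cases = 1)
  # indication-overlap terms and non-signals never enter
  expect_false(any(tr$ae == "Suicidal ideation"))
  expect_false(any(tr$ae == "Sedation"))
  # risperidone co-reported (suspect role) with vertigo in case 1 only
  expect_equal(tr$n_co_cases[tr$ae == "Vertigo" & tr$drug_b == "risperidone"],
               1)
  # the floor of 3 removes it
  tr3 <- select_eligible_triples(b, fl, signals, tiny_cd(), min_co_cases = 3)
  expect_equal(nrow(tr3), 0)
  # a drug reported only as concomitant is never a candidate
  expect_false("ibuprofen" %in% tr$drug_b[tr$ae == "Vertigo"])
})

test_that("verdicts combine the five decision rules", {
  triples <- tibble::tibble(ae = "Vertigo", drug_b = "x")
  strong <- ddi_count_set(n_AB1 = 30, n_A1 = 40, n_AB_plus = 50,
                          n_B_plus = 0, n_plusplus = 1000,
                          n11 = 30, N11 = 50, n10 = 40, N10 = 950,
                          n01 = 20, N01 = 500, n00 = 180, N00 = 18500)
  out <- screen_ddi(triples, list(strong))
  expect_true(out$verdict_all)
  expect_true(out$verdict_arm_strict)
  # lift below 1 sinks the rule verdict whatever the rest says
  weak <- ddi_count_set(n_AB1 = 2, n_A1 = 68, n_AB_plus = 50, n_B_plus = 0,
                        n_plusplus = 1000,
                        n11 = 2, N11 = 50, n10 = 68, N10 = 950,
                        n01 = 20, N01 = 500, n00 = 180, N00 = 18500)
  out2 <- screen_ddi(triples, list(weak))
  expect_false(out2$verdict_arm)
  expect_false(out2$verdict_all)
})

test_that("lift and conviction concentrate at 1 under independence", {
  set.seed(77)
  n <- 50000
  reps <- 60
  lifts <- convs <- numeric(reps)
  for (i in seq_len(reps)) {
    # independent B exposure and AE among a case universe
    b <- runif(n) < 0.2
    ae <- runif(n) < 0.1
    ct <- ddi_count_set(
      n_AB1 = sum(b & ae), n_A1 = sum(!b & ae), n_AB_plus = sum(b),
      n_B_plus = 0, n_plusplus = n,
      n11 = sum(b & ae), N11 = sum(b), n10 = sum(!b & ae), N10 = sum(!b),
      n01 = 1, N01 = 10, n00 = 1, N00 = 10
    )
    lifts[i] <- ddi_lift(ct)
    convs[i] <- ddi_conviction(ct)
  }
  expect_lt(abs(mean(lifts) - 1), 0.1)
  expect_lt(abs(mean(convs) - 1), 0.1)
})

test_that("a planted multiplicative interaction is recovered with its verdicts", {
  # study conditions for the recovery experiment: 5,000 reports, exposures
  # 0.15/0.15, baseline risk 0.025, single-drug risk ratios 2 and 2,
  # multiplicative excess 5
  base_cfg <- function(seed) sim_config(
    n_reports = 5000, seed = seed,
    pt_catalog = tibble::tibble(pt = c("Vertigo", "Nausea"),
                                p = c(0.025, 0.10)),
    drug_catalog = tibble::tibble(
      ingredient = c("esketamine", "risperidone", "filler"),
      brand = NA_character_,
      p_exposure = c(0.15, 0.15, 0.5),
      p_ps = c(0.95, 0.6, 0.3), p_ss = c(0.04, 0.2, 0.1),
      p_i = c(0, 0.1, 0), p_c = c(0.01, 0.1, 0.6), p_brand = 0
    ),
    planted_signals = tibble::tibble(
      drug = c("esketamine", "risperidone"), pt = "Vertigo",
      odds_multiplier = c(2, 2)
    ),
    planted_interactions = tibble::tibble(
      drug_a = "esketamine", drug_b = "risperidone", pt = "Vertigo",
      scale = "multiplicative", strength = 5
    ),
    sex_effects = NULL, p_excluded_indication = 0,
    dup_rates = c(caseid = 0, fieldmatch = 0), deleted_rate = 0
  )
  set.seed(101)
  reps <- 100
  ok <- vapply(seq_len(reps), function(i) {
    sim <- simulate_reports(base_cfg(1000 + i))
    fl <- flag_cases(sim$bundle, tiny_cd())
    ct <- ddi_counts(sim$bundle, fl, "risperidone", "Vertigo")
    mi <- multiplicative_interaction(ct)
    out <- screen_ddi(tibble::tibble(ae = "Vertigo", drug_b = "risperidone"),
                      list(ct))
    (mi >= 3 && mi <= 8) && out$verdict_all
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("analytically additive and multiplicative generators give AI = 0 and MI = 1", {
  cfg <- function(scale) sim_config(
    n_reports = 40000, seed = 500,
    pt_catalog = tibble::tibble(pt = "Vertigo", p = 0.05),
    drug_catalog = tibble::tibble(
      ingredient = c("esketamine", "risperidone", "filler"),
      brand = NA_character_,
      p_exposure = c(0.3, 0.3, 0.5), p_ps = 1, p_ss = 0, p_i = 0, p_c = 0,
      p_brand = 0
    ),
    planted_signals = tibble::tibble(
      drug = c("esketamine", "risperidone"), pt = "Vertigo",
      odds_multiplier = c(3, 2)
    ),
    planted_interactions = tibble::tibble(
      drug_a = "esketamine", drug_b = "risperidone", pt = "Vertigo",
      scale = scale, strength = if (scale == "multiplicative") 1 else 1e-9
    ),
    sex_effects = NULL, p_excluded_indication = 0,
    dup_rates = c(caseid = 0, fieldmatch = 0), deleted_rate = 0
  )
  for (scale in c("additive", "multiplicative")) {
    sim <- simulate_reports(cfg(scale))
    fl <- flag_cases(sim$bundle, tiny_cd())
    ct <- ddi_counts(sim$bundle, fl, "risperidone", "Vertigo")
    if (scale == "additive") {
      expect_lt(abs(additive_interaction(ct)), 0.02)
    } else {
      expect_lt(abs(log(multiplicative_interaction(ct))), 0.35)
    }
  }
})
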