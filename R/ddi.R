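#' Construct a drug-drug-interaction count set
#'
#' Holds the counts needed by the five interaction scores for one
#' (target drug A, concomitant drug B, adverse event) triple. The
#' association-rule terms are counted in the chosen report universe:
#' `n_AB1` (A and B with the AE), `n_A1` (A without B, with the AE),
#' `n_AB_plus` (A and B, any AE), `n_B_plus` (B without A, any AE) and
#' `n_plusplus` (universe size). The four exposure cells (`11` A and B,
#' `10` A only, `01` B only, `00` neither), each with its AE count `n_ij`
#' and total `N_ij`, feed the risk-scale measures and are always counted
#' over all reports.
#'
#' @param n_AB1,n_A1,n_AB_plus,n_B_plus,n_plusplus Association-rule
#'   counts.
#' @param n11,N11,n10,N10,n01,N01,n00,N00 Exposure-cell AE counts and
#'   totals.
#' @return An object of class `ddi_count_set`.
#' @export
ddi_count_set <- function(n_AB1, n_A1, n_AB_plus, n_B_plus, n_plusplus,
                          n11, N11, n10, N10, n01, N01, n00, N00) {
  n_AB1 <- unname(n_AB1); n_A1 <- unname(n_A1)
  n_AB_plus <- unname(n_AB_plus); n_B_plus <- unname(n_B_plus)
  n_plusplus <- unname(n_plusplus)
  n11 <- unname(n11); N11 <- unname(N11); n10 <- unname(n10)
  N10 <- unname(N10); n01 <- unname(n01); N01 <- unname(N01)
  n00 <- unname(n00); N00 <- unname(N00)
  if (n_AB1 > n_AB_plus) stop("n_AB1 cannot exceed n_AB_plus")
  if (any(c(n11 > N11, n10 > N10, n01 > N01, n00 > N00))) {
    stop("each AE count must not exceed its exposure total")
  }
  structure(
    list(n_AB1 = n_AB1, n_A1 = n_A1, n_AB_plus = n_AB_plus,
         n_B_plus = n_B_plus, n_plusplus = n_plusplus,
         n11 = n11, N11 = N11, n10 = n10, N10 = N10,
         n01 = n01, N01 = N01, n00 = n00, N00 = N00),
    class = "ddi_count_set"
  )
}

#' Count a (drug A, drug B, AE) triple in a report bundle
#'
#' Drug A exposure is case status under the analysis case definition;
#' drug B exposure requires a drug row with the B ingredient in a
#' suspect/interacting role. The association-rule universe defaults to
#' case reports (so confidence is the probability of the AE given B among
#' cases); exposure cells are always counted over all reports, since a
#' case-only universe has no A-unexposed cell.
#'
#' @param bundle A deduplicated `report_bundle`.
#' @param flags Case flags from [flag_cases()].
#' @param drug_b Concomitant ingredient name.
#' @param ae Reaction term.
#' @param universe `"case_reports"` (default) or `"all_reports"` for the
#'   association-rule counts.
#' @param roles Roles qualifying as B exposure (default PS, SS, I).
#' @return A [ddi_count_set()].
#' @export
ddi_counts <- function(bundle, flags, drug_b, ae,
                       universe = c("case_reports", "all_reports"),
                       roles = c("PS", "SS", "I")) {
  universe <- match.arg(universe)
  pids <- bundle$demo$primaryid
  is_case <- flags$is_case[match(pids, flags$primaryid)]

  drug <- bundle$drug
  ing <- norm_key(dplyr::coalesce(drug$ingredient, drug$drug_name))
  b_pids <- unique(drug$primaryid[!is.na(ing) & ing == norm_key(drug_b) &
                                    drug$role_code %in% roles])
  has_b <- pids %in% b_pids

  reac <- bundle$reac
  ae_pids <- unique(reac$primaryid[!is.na(reac$pt) &
                                     norm_key(reac$pt) == norm_key(ae)])
  has_ae <- pids %in% ae_pids

  in_u <- if (universe == "case_reports") is_case else rep(TRUE, length(pids))
  n_AB1 <- sum(in_u & is_case & has_b & has_ae)
  n_A1 <- sum(in_u & is_case & !has_b & has_ae)
  n_AB_plus <- sum(in_u & is_case & has_b)
  n_B_plus <- sum(in_u & !is_case & has_b)
  n_plusplus <- sum(in_u)

  cell <- function(a_e, b_e) {
    sel <- (is_case == a_e) & (has_b == b_e)
    c(n = sum(sel & has_ae), N = sum(sel))
  }
  c11 <- cell(TRUE, TRUE); c10 <- cell(TRUE, FALSE)
  c01 <- cell(FALSE, TRUE); c00 <- cell(FALSE, FALSE)
  ddi_count_set(n_AB1, n_A1, n_AB_plus, n_B_plus, n_plusplus,
                c11["n"], c11["N"], c10["n"], c10["N"],
                c01["n"], c01["N"], c00["n"], c00["N"])
}

rule_terms <- function(counts) {
  denom_b <- counts$n_AB_plus + counts$n_B_plus
  list(
    confidence = if (denom_b > 0) counts$n_AB1 / denom_b else NA_real_,
    support = if (counts$n_plusplus > 0)
      (counts$n_AB1 + counts$n_A1) / counts$n_plusplus else NA_real_
  )
}

#' Association-rule lift for a drug pair and adverse event
#'
#' Lift compares the probability of the drug-A-with-AE event given drug B
#' exposure (the rule's confidence) with its marginal probability (the
#' rule's support): `lift = confidence / support`. Lift above 1 means B
#' exposure and the A-with-AE event are positively associated.
#'
#' @param counts A [ddi_count_set()].
#' @return The lift score, or NA when a denominator is empty.
#' @export
ddi_lift <- function(counts) {
  t <- rule_terms(counts)
  if (is.na(t$confidence) || is.na(t$support) || t$support == 0) {
    return(NA_real_)
  }
  t$confidence / t$support
}

#' Association-rule conviction for a drug pair and adverse event
#'
#' Conviction compares the expected and observed rate of rule failures:
#' `conviction = (1 - support) / (1 - confidence)`. Values above 1
#' indicate the rule fails less often than under independence. A
#' confidence of exactly 1 yields `Inf`.
#'
#' @inheritParams ddi_lift
#' @return The conviction score (possibly `Inf`), or NA when not
#'   estimable.
#' @export
ddi_conviction <- function(counts) {
  t <- rule_terms(counts)
  if (is.na(t$confidence) || is.na(t$support)) return(NA_real_)
  if (t$confidence == 1) return(Inf)
  (1 - t$support) / (1 - t$confidence)
}

cell_risks <- function(counts) {
  with(counts, {
    if (any(c(N11, N10, N01, N00) == 0)) return(NULL)
    list(p11 = n11 / N11, p10 = n10 / N10, p01 = n01 / N01, p00 = n00 / N00)
  })
}

#' Additive-scale interaction score
#'
#' With cell risks `p_ij` (AE probability under exposure to A and/or B),
#' the additive interaction is the excess of the joint risk difference
#' over the sum of the single-exposure risk differences:
#' `AI = (p11 - p00) - [(p10 - p00) + (p01 - p00)] = p11 - p10 - p01 + p00`.
#' `AI > 0` flags super-additive risk.
#'
#' @inheritParams ddi_lift
#' @return The AI score, or NA when an exposure cell is empty.
#' @export
additive_interaction <- function(counts) {
  p <- cell_risks(counts)
  if (is.null(p)) return(NA_real_)
  p$p11 - p$p10 - p$p01 + p$p00
}

#' Multiplicative-scale interaction score
#'
#' The ratio of the joint risk ratio to the product of the single-exposure
#' risk ratios: `MI = (p11/p00) / [(p10/p00) * (p01/p00)]
#' = p11 * p00 / (p10 * p01)`. `MI > 1` flags super-multiplicative risk.
#'
#' @inheritParams ddi_lift
#' @return The MI score, or NA when a required cell risk is zero or an
#'   exposure cell is empty.
#' @export
multiplicative_interaction <- function(counts) {
  p <- cell_risks(counts)
  if (is.null(p) || p$p10 == 0 || p$p01 == 0 || p$p00 == 0) {
    return(NA_real_)
  }
  p$p11 * p$p00 / (p$p10 * p$p01)
}

prr_ratio <- function(n_e, N_e, n_total, N_total) {
  n_u <- n_total - n_e
  N_u <- N_total - N_e
  if (N_e == 0 || N_u == 0 || n_u == 0) return(NA_real_)
  (n_e / N_e) / (n_u / N_u)
}

#' Combination risk ratio
#'
#' The PRR of the drug combination divided by the larger of the two
#' single-drug PRRs: `CRR = PRR_{A and B} / max(PRR_A, PRR_B)`. Each PRR
#' contrasts one exposure cell against all remaining reports, with the
#' single-drug PRRs taken from the drug-without-the-other cells (A not B,
#' B not A) so that, when both drugs double the event rate and the
#' combination quadruples it, CRR sits at its signal boundary of 2.
#' `CRR > 2` flags a combination signal.
#'
#' @inheritParams ddi_lift
#' @return The CRR score, or NA when any component PRR is non-estimable.
#' @export
combination_risk_ratio <- function(counts) {
  with(counts, {
    n_total <- n11 + n10 + n01 + n00
    N_total <- N11 + N10 + N01 + N00
    prr_ab <- prr_ratio(n11, N11, n_total, N_total)
    prr_a <- prr_ratio(n10, N10, n_total, N_total)
    prr_b <- prr_ratio(n01, N01, n_total, N_total)
    if (anyNA(c(prr_ab, prr_a, prr_b)) || max(prr_a, prr_b) == 0) {
      return(NA_real_)
    }
    prr_ab / max(prr_a, prr_b)
  })
}

#' Select the (AE, drug B) triples eligible for interaction scoring
#'
#' A triple is eligible when the AE is itself a disproportionality signal,
#' is not on the exclusion list of terms overlapping the treated
#' indication, and drug B (any ingredient other than the target) appears
#' in a suspect or interacting role in at least `min_co_cases` case
#' reports carrying that AE. Drugs reported only as concomitant never
#' qualify.
#'
#' @param bundle A deduplicated `report_bundle`.
#' @param flags Case flags from [flag_cases()].
#' @param signals A signal tibble from [screen_signals()].
#' @param cd The [case_definition()] (identifies the target ingredient).
#' @param exclusions AE terms excluded as indication-related.
#' @param min_co_cases Minimum co-reporting case count (default 3).
#' @param roles Roles qualifying as B exposure.
#' @return A tibble `(ae, drug_b, n_co_cases)`.
#' @export
select_eligible_triples <- function(bundle, flags, signals, cd,
                                    exclusions = c(
                                      "anxiety", "depression",
                                      "panic attack", "completed suicide",
                                      "suicidal ideation", "suicide attempt"
                                    ),
                                    min_co_cases = 3,
                                    roles = c("PS", "SS", "I")) {
  aes <- signals$pt[signals$is_signal &
                      !(norm_key(signals$pt) %in% norm_key(exclusions))]
  if (!length(aes)) {
    return(tibble::tibble(ae = character(), drug_b = character(),
                          n_co_cases = integer()))
  }
  case_pids <- flags$primaryid[flags$is_case]
  reac <- bundle$reac
  mem <- dplyr::distinct(tibble::tibble(
    primaryid = reac$primaryid, pt_key = norm_key(reac$pt)
  ))
  mem <- mem[mem$primaryid %in% case_pids &
               mem$pt_key %in% norm_key(aes), ]

  drug <- bundle$drug
  ing <- norm_key(dplyr::coalesce(drug$ingredient, drug$drug_name))
  bd <- tibble::tibble(primaryid = drug$primaryid, ingredient = ing)[
    !is.na(ing) & ing != norm_key(cd$target_ingredient) &
      drug$role_code %in% roles, ]
  bd <- dplyr::distinct(bd)

  co <- dplyr::inner_join(mem, bd, by = "primaryid",
                          relationship = "many-to-many") |>
    dplyr::count(.data$pt_key, .data$ingredient, name = "n_co_cases") |>
    dplyr::filter(.data$n_co_cases >= min_co_cases)
  disp <- stats::setNames(aes, norm_key(aes))
  tibble::tibble(ae = unname(disp[co$pt_key]), drug_b = co$ingredient,
                 n_co_cases = co$n_co_cases)
}

#' Score and screen drug-drug-interaction triples
#'
#' Computes the five interaction scores for each triple and applies the
#' decision rules: an association rule requires lift > 1 and
#' conviction > 1 (with a stricter lift threshold as sensitivity
#' analysis); additive interaction requires AI > 0, multiplicative
#' MI > 1, and the combination risk ratio CRR > 2. All verdicts use the
#' unrounded scores; `verdict_all` is their conjunction (the strict lift
#' bound is reported separately). Every evaluated triple is kept in the
#' output; a non-estimable score makes `verdict_all` FALSE.
#'
#' @param counts_by_triple A named list or tibble pairing each triple
#'   with its [ddi_count_set()]; most callers use [ddi_analysis()].
#' @param triples The tibble from [select_eligible_triples()].
#' @param thresholds Named list of rule thresholds.
#' @return A tibble with counts, the five scores and the verdict columns.
#' @export
screen_ddi <- function(triples, counts_by_triple,
                       thresholds = list(lift = 1, lift_strict = 2,
                                         conviction = 1, ai = 0, mi = 1,
                                         crr = 2)) {
  score_one <- function(i) {
    ct <- counts_by_triple[[i]]
    lift <- ddi_lift(ct)
    conviction <- ddi_conviction(ct)
    ai <- additive_interaction(ct)
    mi <- multiplicative_interaction(ct)
    crr <- combination_risk_ratio(ct)
    v_arm <- isTRUE(lift > thresholds$lift) &
      isTRUE(conviction > thresholds$conviction)
    v_strict <- isTRUE(lift > thresholds$lift_strict)
    v_ai <- isTRUE(ai > thresholds$ai)
    v_mi <- isTRUE(mi > thresholds$mi)
    v_crr <- isTRUE(crr > thresholds$crr)
    tibble::tibble(
      ae = triples$ae[i], drug_b = triples$drug_b[i],
      n_ae_cases = ct$n_AB1 + ct$n_A1, n_b = ct$n_AB_plus + ct$n_B_plus,
      n_both_ae = ct$n_AB1,
      lift = lift, conviction = conviction, ai = ai, mi = mi, crr = crr,
      verdict_arm = v_arm, verdict_arm_strict = v_strict,
      verdict_ai = v_ai, verdict_mi = v_mi, verdict_crr = v_crr,
      verdict_all = v_arm & v_ai & v_mi & v_crr
    )
  }
  if (nrow(triples) == 0) {
    return(tibble::tibble(
      ae = character(), drug_b = character(), n_ae_cases = numeric(),
      n_b = numeric(), n_both_ae = numeric(), lift = numeric(),
      conviction = numeric(), ai = numeric(), mi = numeric(),
      crr = numeric(), verdict_arm = logical(),
      verdict_arm_strict = logical(), verdict_ai = logical(),
      verdict_mi = logical(), verdict_crr = logical(),
      verdict_all = logical()
    ))
  }
  dplyr::bind_rows(lapply(seq_len(nrow(triples)), score_one))
}

#' End-to-end drug-drug-interaction analysis
#'
#' Selects eligible (AE, drug B) triples from the screened signals,
#' counts each triple and applies the five-score screen.
#'
#' @inheritParams select_eligible_triples
#' @inheritParams ddi_counts
#' @inheritParams screen_ddi
#' @return The score tibble from [screen_ddi()].
#' @export
ddi_analysis <- function(bundle, flags, signals, cd,
                         exclusions = c("anxiety", "depression",
                                        "panic attack", "completed suicide",
                                        "suicidal ideation",
                                        "suicide attempt"),
                         min_co_cases = 3,
                         universe = c("case_reports", "all_reports"),
                         roles = c("PS", "SS", "I"),
                         thresholds = list(lift = 1, lift_strict = 2,
                                           conviction = 1, ai = 0, mi = 1,
                                           crr = 2)) {
  universe <- match.arg(universe)
  triples <- select_eligible_triples(bundle, flags, signals, cd,
                                     exclusions = exclusions,
                                     min_co_cases = min_co_cases,
                                     roles = roles)
  counts <- lapply(seq_len(nrow(triples)), function(i) {
    ddi_counts(bundle, flags, triples$drug_b[i], triples$ae[i],
               universe = universe, roles = roles)
  })
  screen_ddi(triples, counts, thresholds = thresholds)
}
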