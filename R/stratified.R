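#' Convert reported age to years
#'
#' Honors the FAERS age-unit codes: years pass through, decades are
#' multiplied by 10, months/weeks/days are divided by 12 / 52.14 / 365.25.
#' A blank unit is treated as years (the database convention); an unknown
#' non-blank code makes the age missing and is counted in attribute
#' `n_unknown_unit`.
#'
#' @param age Numeric vector of reported ages.
#' @param age_unit Character vector of unit codes (`YR`, `DEC`, `MON`,
#'   `WK`, `DY`, `HR`).
#' @return Numeric vector of ages in years.
#' @export
convert_age_years <- function(age, age_unit) {
  unit <- toupper(trimws(as.character(age_unit)))
  unit[is.na(unit) | unit == ""] <- "YR"
  factor <- c(YR = 1, YEAR = 1, DEC = 10, MON = 1 / 12, MO = 1 / 12,
              WK = 1 / 52.14, DY = 1 / 365.25, HR = 1 / 8766)
  f <- factor[unit]
  out <- as.numeric(age) * as.numeric(f)
  attr(out, "n_unknown_unit") <- sum(is.na(f) & !is.na(age))
  out
}

#' Assign reports to analysis strata
#'
#' Sex strata are `F` and `M`; the age strata are adults (18-64 years
#' inclusive) and older adults (65 and over). Reports with a missing or
#' out-of-range stratum value get `NA` and are excluded from stratified
#' analyses only (they remain in the main analysis). With
#' `age_years_only = TRUE` (the default) only reports whose age unit is
#' explicitly years enter the age strata.
#'
#' @param bundle A `report_bundle`.
#' @param variable `"sex"` or `"age_group"`.
#' @param age_years_only Restrict the age analysis to ages reported in
#'   years.
#' @return A tibble `(primaryid, stratum)`.
#' @export
stratify_reports <- function(bundle, variable = c("sex", "age_group"),
                             age_years_only = TRUE) {
  variable <- match.arg(variable)
  demo <- bundle$demo
  if (variable == "sex") {
    s <- toupper(trimws(demo$sex))
    stratum <- ifelse(s %in% c("F", "M"), s, NA_character_)
  } else {
    if (age_years_only) {
      unit_ok <- toupper(trimws(dplyr::coalesce(demo$age_unit, ""))) %in%
        c("YR", "YEAR")
      yrs <- ifelse(unit_ok, demo$age, NA_real_)
    } else {
      yrs <- convert_age_years(demo$age, demo$age_unit)
    }
    stratum <- dplyr::case_when(
      is.na(yrs) ~ NA_character_,
      yrs >= 65 ~ "older_adult",
      yrs >= 18 ~ "adult",
      TRUE ~ NA_character_
    )
  }
  tibble::tibble(primaryid = demo$primaryid, stratum = stratum)
}

rel_ror_stats <- function(r1, r2, se1, se2, ci_level = 0.95, z = NULL) {
  z <- z %||% stats::qnorm(1 - (1 - ci_level) / 2)
  rel <- r1 / r2
  se <- sqrt(se1^2 + se2^2)
  tibble::tibble(rel_ror = rel,
                 rel_ci_low = exp(log(rel) - z * se),
                 rel_ci_high = exp(log(rel) + z * se))
}

classify_rule <- function(ci_low1, ci_low2, rel_lo, rel_hi) {
  dplyr::case_when(
    is.na(rel_lo) | is.na(ci_low1) | is.na(ci_low2) ~ "not_evaluable",
    ci_low1 > 1 & rel_lo > 1 ~ "stratum1_higher",
    ci_low2 > 1 & rel_hi < 1 ~ "stratum2_higher",
    TRUE ~ "no_difference"
  )
}

#' Relative ROR between two strata
#'
#' The relative ROR of stratum 1 versus stratum 2 is the ratio of the two
#' stratum RORs; its CI combines both stratum variances on the log scale:
#' `exp(log(ROR1/ROR2) +/- z * sqrt(sum of the eight reciprocal cells))`.
#' The decision rule flags stratum 1 as higher when both the stratum-1 ROR
#' lower bound and the relative-ROR lower bound exceed 1 (and
#' symmetrically for stratum 2). The point estimate is always formed from
#' the unrounded stratum RORs.
#'
#' @param r1,r2 `signal_result` objects for the two strata, or bare
#'   numeric ROR values (in which case no CI or classification is
#'   possible).
#' @param ci_level Confidence level.
#' @param z Optional explicit normal multiplier (see [ror()]).
#' @param labels Length-2 character vector naming the strata.
#' @param min_reports Report floor required in both strata for the
#'   comparison to be evaluable.
#' @return An object of class `stratified_comparison`.
#' @export
relative_ror <- function(r1, r2, ci_level = 0.95, z = NULL,
                         labels = c("stratum1", "stratum2"),
                         min_reports = 5) {
  if (is.numeric(r1) && is.numeric(r2)) {
    return(structure(
      list(pt = NA_character_, stratum1 = labels[1], stratum2 = labels[2],
           result1 = NULL, result2 = NULL, rel_ror = r1 / r2,
           rel_ci_low = NA_real_, rel_ci_high = NA_real_,
           classification = "not_evaluable"),
      class = "stratified_comparison"
    ))
  }
  stopifnot(inherits(r1, "signal_result"), inherits(r2, "signal_result"))
  evaluable <- r1$n_reports >= min_reports && r2$n_reports >= min_reports &&
    r1$estimable && r2$estimable
  if (!evaluable) {
    rel <- tibble::tibble(rel_ror = NA_real_, rel_ci_low = NA_real_,
                          rel_ci_high = NA_real_)
    cls <- "not_evaluable"
  } else {
    se1 <- sqrt(1 / r1$a + 1 / r1$b + 1 / r1$c + 1 / r1$d)
    se2 <- sqrt(1 / r2$a + 1 / r2$b + 1 / r2$c + 1 / r2$d)
    rel <- rel_ror_stats(r1$ror, r2$ror, se1, se2, ci_level, z)
    cls <- classify_rule(r1$ci_low, r2$ci_low, rel$rel_ci_low,
                         rel$rel_ci_high)
  }
  structure(
    list(pt = r1$pt %||% r2$pt, stratum1 = labels[1], stratum2 = labels[2],
         result1 = r1, result2 = r2, rel_ror = rel$rel_ror,
         rel_ci_low = rel$rel_ci_low, rel_ci_high = rel$rel_ci_high,
         classification = cls),
    class = "stratified_comparison"
  )
}

#' @export
print.stratified_comparison <- function(x, ...) {
  cat(sprintf(
    "<stratified_comparison> %s %s/%s: rel ROR = %.3g (%.3g-%.3g), %s\n",
    x$pt %||% "", x$stratum1, x$stratum2, x$rel_ror, x$rel_ci_low,
    x$rel_ci_high, x$classification))
  invisible(x)
}

#' Stratified disproportionality analysis
#'
#' Splits the bundle by sex (women vs men) or age group (older adults vs
#' adults), computes the stratum-specific RORs for every reaction term
#' with at least `min_reports` case reports in both strata, and derives
#' the relative ROR with its combined CI and classification.
#' Missing-stratum reports are excluded here only. The `signal_in` column
#' records in which strata the term is itself a signal (lower CI bound
#' above 1), so terms significant exclusively in one stratum can be read
#' off directly.
#'
#' @param bundle A deduplicated `report_bundle`.
#' @param flags Case flags from [flag_cases()].
#' @param variable `"sex"` or `"age_group"`.
#' @param min_reports Per-stratum case-report floor (default 5).
#' @inheritParams relative_ror
#' @param age_years_only See [stratify_reports()].
#' @return A tibble with one row per evaluable term: stratum counts and
#'   RORs, relative ROR with CI, `classification`, `signal_in`.
#' @export
stratified_analysis <- function(bundle, flags,
                                variable = c("sex", "age_group"),
                                min_reports = 5, ci_level = 0.95, z = NULL,
                                age_years_only = TRUE) {
  variable <- match.arg(variable)
  strata <- if (variable == "sex") c("F", "M") else c("older_adult", "adult")
  sm <- stratify_reports(bundle, variable, age_years_only = age_years_only)

  per_stratum <- lapply(strata, function(s) {
    pids <- sm$primaryid[!is.na(sm$stratum) & sm$stratum == s]
    sub <- filter_bundle(bundle, pids)
    f <- flags[flags$primaryid %in% pids, ]
    build_contingency_all(sub, f) |>
      dplyr::mutate(pt_key = norm_key(.data$pt))
  })
  t1 <- per_stratum[[1]]; t2 <- per_stratum[[2]]
  j <- dplyr::inner_join(t1, t2, by = "pt_key", suffix = c("1", "2"))
  j <- j[j$a1 >= min_reports & j$a2 >= min_reports, ]
  if (nrow(j) == 0) {
    return(tibble::tibble(
      pt = character(), stratum1 = character(), stratum2 = character(),
      a1 = numeric(), ror1 = numeric(), ci1_low = numeric(),
      ci1_high = numeric(), a2 = numeric(), ror2 = numeric(),
      ci2_low = numeric(), ci2_high = numeric(), rel_ror = numeric(),
      rel_ci_low = numeric(), rel_ci_high = numeric(),
      classification = character(), signal_in = character()
    ))
  }
  s1 <- ror_stats(j$a1, j$b1, j$c1, j$d1, ci_level, z)
  s2 <- ror_stats(j$a2, j$b2, j$c2, j$d2, ci_level, z)
  rel <- rel_ror_stats(s1$ror, s2$ror, s1$se_log, s2$se_log, ci_level, z)
  sig1 <- s1$estimable & s1$ci_low > 1
  sig2 <- s2$estimable & s2$ci_low > 1
  tibble::tibble(
    pt = j$pt1, stratum1 = strata[1], stratum2 = strata[2],
    a1 = j$a1, ror1 = s1$ror, ci1_low = s1$ci_low, ci1_high = s1$ci_high,
    a2 = j$a2, ror2 = s2$ror, ci2_low = s2$ci_low, ci2_high = s2$ci_high,
    rel_ror = rel$rel_ror, rel_ci_low = rel$rel_ci_low,
    rel_ci_high = rel$rel_ci_high,
    classification = classify_rule(s1$ci_low, s2$ci_low, rel$rel_ci_low,
                                   rel$rel_ci_high),
    signal_in = dplyr::case_when(
      sig1 & sig2 ~ "both", sig1 ~ "stratum1", sig2 ~ "stratum2",
      TRUE ~ "neither"
    )
  )
}

#' Forest-plot data export for a stratified analysis
#'
#' Returns the classified terms with the relative ROR oriented so the
#' higher-reporting stratum is in the numerator, ready to be drawn as a
#' forest plot by any plotting front end.
#'
#' @param stratified A tibble from [stratified_analysis()].
#' @return A tibble `(pt, direction, rel_ror, ci_low, ci_high)` restricted
#'   to terms classified as different between strata.
#' @export
forest_data <- function(stratified) {
  s <- stratified[stratified$classification %in%
                    c("stratum1_higher", "stratum2_higher"), ]
  flip <- s$classification == "stratum2_higher"
  tibble::tibble(
    pt = s$pt,
    direction = ifelse(flip, s$stratum2, s$stratum1),
    rel_ror = ifelse(flip, 1 / s$rel_ror, s$rel_ror),
    ci_low = ifelse(flip, 1 / s$rel_ci_high, s$rel_ci_low),
    ci_high = ifelse(flip, 1 / s$rel_ci_low, s$rel_ci_high)
  )
}
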