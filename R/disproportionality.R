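#' Vectorised ROR / Woolf-CI machinery shared by the user-facing helpers.
#'
#' @noRd
ror_stats <- function(a, b, c, d, ci_level = 0.95, z = NULL) {
  z <- z %||% stats::qnorm(1 - (1 - ci_level) / 2)
  estimable <- a > 0 & b > 0 & c > 0 & d > 0
  est <- rep(NA_real_, length(a))
  est[estimable] <- (a[estimable] * d[estimable]) /
    (b[estimable] * c[estimable])
  # zero target-AE count among cases: point estimate 0; c = 0 stays NA
  zero_a <- !estimable & a == 0 & b > 0 & c > 0 & d > 0
  est[zero_a] <- 0
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  lo <- ifelse(estimable, exp(log(est) - z * se), NA_real_)
  hi <- ifelse(estimable, exp(log(est) + z * se), NA_real_)
  tibble::tibble(ror = est, ci_low = lo, ci_high = hi,
                 se_log = ifelse(estimable, se, NA_real_),
                 estimable = estimable)
}

new_signal_result <- function(pt, a, b, c, d, est, ci_low, ci_high,
                              ci_level, estimable, measure,
                              is_signal = NA) {
  structure(
    list(pt = pt, a = a, b = b, c = c, d = d, ror = est, ci_low = ci_low,
         ci_high = ci_high, ci_level = ci_level, n_reports = a,
         estimable = estimable, is_signal = is_signal, measure = measure),
    class = "signal_result"
  )
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("<signal_result> %s %s = %.4g (%.4g-%.4g), n = %d\n",
              x$measure, x$pt %||% "", x$ror, x$ci_low, x$ci_high,
              x$n_reports))
  invisible(x)
}

#' Reporting odds ratio with Woolf confidence interval
#'
#' Computes `ROR = (a/c) / (b/d)` and the log-normal (Woolf) interval
#' `exp(log(ROR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. A table with any
#' empty cell is flagged non-estimable (no continuity correction is
#' applied; a zero `a` gives point estimate 0 with no interval).
#'
#' @param table A [contingency_table()].
#' @param ci_level Confidence level as a fraction (default 0.95).
#' @param z Optional explicit normal multiplier. The default derives z
#'   from `ci_level` via the normal quantile; pass `z = 1.96` to apply the
#'   conventional two-decimal multiplier used in published
#'   disproportionality tables.
#' @return A `signal_result` (point estimate, CI bounds, counts,
#'   estimability flag).
#' @export
#' @examples
#' ror(contingency_table(a = 5, b = 95, c = 50, d = 950))
ror <- function(table, ci_level = 0.95, z = NULL) {
  stopifnot(inherits(table, "contingency_table"))
  s <- ror_stats(table$a, table$b, table$c, table$d, ci_level, z)
  new_signal_result(table$pt, table$a, table$b, table$c, table$d,
                    s$ror, s$ci_low, s$ci_high, ci_level, s$estimable,
                    measure = "ROR")
}

#' Proportional reporting ratio
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; used as the building block of the
#' combination risk ratio. No interval is attached. A zero `c` makes the
#' ratio non-estimable; a zero `a` gives 0.
#'
#' @inheritParams ror
#' @return A `signal_result` with `measure = "PRR"`.
#' @export
prr <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  estimable <- (a + b) > 0 & (c + d) > 0 & c > 0
  est <- if (estimable) (a / (a + b)) / (c / (c + d)) else NA_real_
  if (!estimable && a == 0 && (a + b) > 0) est <- 0
  new_signal_result(table$pt, a, b, c, d, est, NA_real_, NA_real_,
                    NA_real_, estimable, measure = "PRR")
}

#' Screen reaction terms for disproportionality signals
#'
#' Applies the report floor and the lower-bound rule: a term is a signal
#' when it has at least `min_reports` case reports and the lower limit of
#' its CI strictly exceeds 1. Terms below the floor are excluded from the
#' output; non-estimable terms are carried with `is_signal = FALSE` and
#' `estimable = FALSE`, never silently dropped.
#'
#' @param tables A tibble `(pt, a, b, c, d)` as from
#'   [build_contingency_all()], or a list of [contingency_table()].
#' @param min_reports Minimum case-report count (default 5).
#' @inheritParams ror
#' @return A tibble `(pt, a, b, c, d, ror, ci_low, ci_high, n_reports,
#'   estimable, is_signal)` sorted by decreasing ROR.
#' @export
screen_signals <- function(tables, min_reports = 5, ci_level = 0.95,
                           z = NULL) {
  if (is.list(tables) && !is.data.frame(tables)) {
    tables <- dplyr::bind_rows(lapply(tables, function(t) {
      tibble::tibble(pt = t$pt, a = t$a, b = t$b, c = t$c, d = t$d)
    }))
  }
  tables <- tables[tables$a >= min_reports, ]
  s <- ror_stats(tables$a, tables$b, tables$c, tables$d, ci_level, z)
  out <- tibble::tibble(
    pt = tables$pt, a = tables$a, b = tables$b, c = tables$c, d = tables$d,
    ror = s$ror, ci_low = s$ci_low, ci_high = s$ci_high,
    n_reports = tables$a, estimable = s$estimable,
    is_signal = s$estimable & !is.na(s$ci_low) & s$ci_low > 1
  )
  out[order(-ifelse(is.na(out$ror), -Inf, out$ror)), ]
}

#' Comparator-restricted sensitivity analysis
#'
#' Re-runs the screening with the non-case population restricted to
#' reports mentioning a comparator ingredient (with the same eligible
#' roles) and not the target. Reports carrying both target and comparator
#' count as cases by default, mirroring the main analysis' case
#' definition.
#'
#' @param bundle A deduplicated `report_bundle`.
#' @param cd Target [case_definition()].
#' @param comparator_ingredient Comparator active ingredient.
#' @param keep_coexposed Keep target-and-comparator co-reports as cases
#'   (default TRUE); if FALSE they are dropped from the universe.
#' @inheritParams screen_signals
#' @return A signal tibble as from [screen_signals()].
#' @export
comparator_analysis <- function(bundle, cd, comparator_ingredient,
                                min_reports = 5, ci_level = 0.95, z = NULL,
                                keep_coexposed = TRUE) {
  drug <- bundle$drug
  ing <- norm_key(dplyr::coalesce(drug$ingredient, drug$drug_name))
  comp <- norm_key(comparator_ingredient)
  comp_any <- unique(drug$primaryid[!is.na(ing) & ing == comp &
                                      drug$role_code %in% cd$eligible_roles])
  if (!length(comp_any)) {
    stop("comparator ingredient '", comparator_ingredient,
         "' absent from bundle")
  }
  tgt_any <- unique(drug$primaryid[!is.na(ing) &
                                     ing == norm_key(cd$target_ingredient)])
  flags <- flag_cases(bundle, cd)
  case_pids <- flags$primaryid[flags$is_case]
  noncase_pids <- setdiff(comp_any, tgt_any)
  if (!length(noncase_pids)) {
    stop("no comparator-only reports for '", comparator_ingredient,
         "' after restriction")
  }
  if (!keep_coexposed) case_pids <- setdiff(case_pids, comp_any)
  universe <- c(case_pids, noncase_pids)
  sub <- filter_bundle(bundle, universe)
  subflags <- tibble::tibble(primaryid = sub$demo$primaryid,
                             is_case = sub$demo$primaryid %in% case_pids)
  screen_signals(build_contingency_all(sub, subflags),
                 min_reports = min_reports, ci_level = ci_level, z = z)
}
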