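#' Time-to-onset for case reports
#'
#' Time-to-onset (TTO) is the difference in days between the start of
#' therapy with the target drug and the event date. Only day-precision
#' dates can yield a defined difference, so records whose start or event
#' date is missing or partial are counted as unavailable; when several
#' therapy rows exist for the target drug the earliest day-precision start
#' is used. Negative differences indicate data errors and are excluded
#' (and counted), not clamped.
#'
#' @param bundle A deduplicated `report_bundle`.
#' @param flags Case flags from [flag_cases()].
#' @param cd The [case_definition()] identifying the target drug.
#' @return A tibble `(primaryid, start_date, event_date, tto_days)` with
#'   one row per case having both dates, and counter attributes
#'   `n_negative` and `n_unavailable`.
#' @export
compute_tto <- function(bundle, flags, cd) {
  case_pids <- flags$primaryid[flags$is_case]
  drug <- bundle$drug
  ing <- norm_key(dplyr::coalesce(drug$ingredient, drug$drug_name))
  tkeys <- paste(drug$primaryid, drug$drug_seq)[
    !is.na(ing) & ing == norm_key(cd$target_ingredient)
  ]
  ther <- bundle$ther
  tther <- ther[paste(ther$primaryid, ther$drug_seq) %in% tkeys &
                  ther$primaryid %in% case_pids, ]
  sd <- parse_partial_date(tther$start_dt)
  tther$start_date <- partial_date_to_date(sd)
  starts <- tther[!is.na(tther$start_date), ] |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(start_date = min(.data$start_date), .groups = "drop")

  demo <- bundle$demo[bundle$demo$primaryid %in% case_pids, ]
  ed <- parse_partial_date(demo$event_dt)
  events <- tibble::tibble(primaryid = demo$primaryid,
                           event_date = partial_date_to_date(ed))
  out <- dplyr::inner_join(starts, events, by = "primaryid")
  out <- out[!is.na(out$event_date), ]
  out$tto_days <- as.integer(out$event_date - out$start_date)
  n_negative <- sum(out$tto_days < 0)
  out <- out[out$tto_days >= 0,
             c("primaryid", "start_date", "event_date", "tto_days")]
  attr(out, "n_negative") <- n_negative
  attr(out, "n_unavailable") <- length(case_pids) - nrow(out) - n_negative
  out
}

#' Classify report seriousness from outcome codes
#'
#' A report is serious when it carries at least one outcome row with a
#' recognised serious-outcome code (DE death, LT life-threatening, HO
#' hospitalisation, DS disability, CA congenital anomaly, RI required
#' intervention, OT other serious). Reports without outcome rows are
#' non-serious. Unrecognised codes are warned about and ignored.
#'
#' @param bundle A `report_bundle`.
#' @return A tibble `(primaryid, serious, outcome_codes)` covering every
#'   report in `demo`.
#' @export
classify_serious <- function(bundle) {
  outc <- bundle$outc
  bad <- !(outc$outcome_code %in% outcome_codes())
  if (any(bad)) {
    warning(sum(bad), " outcome rows with unknown codes ignored")
    outc <- outc[!bad, ]
  }
  codes <- tapply(outc$outcome_code, outc$primaryid,
                  function(x) paste(sort(unique(x)), collapse = ","))
  pids <- bundle$demo$primaryid
  idx <- match(pids, names(codes))
  tibble::tibble(
    primaryid = pids,
    serious = !is.na(idx),
    outcome_codes = ifelse(is.na(idx), "", as.character(codes[idx]))
  )
}

#' Two-group contrast for report characteristics
#'
#' Wraps the standard two-sided tests used to contrast report strata:
#' the Mann-Whitney U test (via [stats::wilcox.test()], with the
#' tie-corrected normal approximation when ties are present) for numeric
#' characteristics, and Pearson's chi-squared test (uncorrected, via
#' [stats::chisq.test()]) for categorical ones.
#'
#' @param x,y The two groups: numeric vectors for `mann_whitney`,
#'   category vectors for `chi_squared`.
#' @param test Which test to run.
#' @param labels Group labels for the summary.
#' @return A list of class `group_comparison`: `test`, `statistic`
#'   (U or X-squared), `p_value`, `n`, and `summary` (group medians or a
#'   proportion table). A group of size zero yields `evaluable = FALSE`.
#' @export
compare_groups <- function(x, y, test = c("mann_whitney", "chi_squared"),
                           labels = c("group1", "group2")) {
  test <- match.arg(test)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    return(structure(list(test = test, statistic = NA_real_,
                          p_value = NA_real_,
                          n = stats::setNames(c(length(x), length(y)), labels),
                          summary = NULL, evaluable = FALSE),
                     class = "group_comparison"))
  }
  if (test == "mann_whitney") {
    ht <- suppressWarnings(stats::wilcox.test(x, y))
    smry <- stats::setNames(c(stats::median(x), stats::median(y)), labels)
  } else {
    grp <- rep(labels, c(length(x), length(y)))
    tab <- table(group = grp, value = c(as.character(x), as.character(y)))
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    smry <- prop.table(tab, margin = 1)
  }
  structure(list(test = test, statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 n = stats::setNames(c(length(x), length(y)), labels),
                 summary = smry, evaluable = TRUE),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic = %.4g, p = %.3g (n = %s)\n",
              x$test, x$statistic, x$p_value,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Serious vs non-serious and sex contrasts among cases
#'
#' Assembles the standard seriousness contrasts for the case series: age,
#' weight and TTO compared between serious and non-serious cases with the
#' Mann-Whitney U test, sex with Pearson's chi-squared test, plus the TTO
#' sex contrast.
#'
#' @param bundle A deduplicated `report_bundle`.
#' @param flags Case flags from [flag_cases()].
#' @param cd The [case_definition()].
#' @return A tibble with one row per contrast: variable, group medians or
#'   proportions, group sizes, statistic and p-value.
#' @export
outcome_contrasts <- function(bundle, flags, cd) {
  case_pids <- flags$primaryid[flags$is_case]
  demo <- bundle$demo[bundle$demo$primaryid %in% case_pids, ]
  ser <- classify_serious(bundle)
  ser <- ser[match(demo$primaryid, ser$primaryid), ]
  tto <- compute_tto(bundle, flags, cd)
  tto_days <- tto$tto_days[match(demo$primaryid, tto$primaryid)]
  age_years <- convert_age_years(demo$age, demo$age_unit)
  sex <- toupper(trimws(demo$sex))
  sex[!(sex %in% c("F", "M"))] <- NA

  row <- function(variable, cmp, g1, g2) {
    tibble::tibble(
      variable = variable, group1 = g1, group2 = g2,
      n1 = unname(cmp$n[1]), n2 = unname(cmp$n[2]),
      summary1 = if (cmp$evaluable && is.numeric(cmp$summary))
        cmp$summary[1] else NA_real_,
      summary2 = if (cmp$evaluable && is.numeric(cmp$summary))
        cmp$summary[2] else NA_real_,
      statistic = cmp$statistic, p_value = cmp$p_value,
      test = cmp$test
    )
  }
  s <- ser$serious
  dplyr::bind_rows(
    row("age_years", compare_groups(age_years[s], age_years[!s],
                                    "mann_whitney",
                                    c("serious", "non_serious")),
        "serious", "non_serious"),
    row("weight_kg", compare_groups(demo$weight[s], demo$weight[!s],
                                    "mann_whitney",
                                    c("serious", "non_serious")),
        "serious", "non_serious"),
    row("tto_days", compare_groups(tto_days[s], tto_days[!s],
                                   "mann_whitney",
                                   c("serious", "non_serious")),
        "serious", "non_serious"),
    row("sex", compare_groups(sex[s], sex[!s], "chi_squared",
                              c("serious", "non_serious")),
        "serious", "non_serious"),
    row("tto_days", compare_groups(tto_days[!is.na(sex) & sex == "F"],
                                   tto_days[!is.na(sex) & sex == "M"],
                                   "mann_whitney", c("F", "M")),
        "F", "M")
  )
}
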