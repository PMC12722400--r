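#' Define the case population
#'
#' A case is a deduplicated report in which the target ingredient appears
#' with an eligible suspect role and none of the target drug's reported
#' indications fall in the exclusion sets. The default keyword exclusions
#' remove anaesthetic/analgesic uses so that the case series reflects
#' psychiatric use of the target drug.
#'
#' @param target_ingredient Active-ingredient name (matched
#'   case-insensitively).
#' @param eligible_roles Subset of `PS`, `SS`, `I`, `C`.
#' @param excluded_indication_pts Exact indication terms to exclude
#'   (case-insensitive).
#' @param excluded_indication_keywords Substrings excluding an indication
#'   (case-insensitive).
#' @return An object of class `case_definition`.
#' @export
case_definition <- function(target_ingredient,
                            eligible_roles = c("PS", "SS"),
                            excluded_indication_pts = character(),
                            excluded_indication_keywords = c(
                              "anaesthesia", "anesthesia", "sedation",
                              "pain", "analgesia", "anaesthetic"
                            )) {
  target_ingredient <- trimws(target_ingredient)
  if (!nzchar(target_ingredient)) stop("target_ingredient must be non-empty")
  eligible_roles <- toupper(eligible_roles)
  if (!length(eligible_roles) || !all(eligible_roles %in% role_codes())) {
    stop("eligible_roles must be a non-empty subset of PS, SS, I, C")
  }
  structure(
    list(target_ingredient = target_ingredient,
         eligible_roles = eligible_roles,
         excluded_indication_pts = excluded_indication_pts,
         excluded_indication_keywords = excluded_indication_keywords),
    class = "case_definition"
  )
}

# Subset every table of a bundle to a set of surviving primaryids.
filter_bundle <- function(bundle, keep_pids) {
  for (nm in c("demo", "drug", "reac", "outc", "ther", "indi")) {
    bundle[[nm]] <- bundle[[nm]][bundle[[nm]]$primaryid %in% keep_pids, ]
  }
  bundle
}

#' Deduplicate reports sharing a case id
#'
#' Among reports with the same `caseid`, the one with the most recent
#' `fda_dt` survives; ties are broken by the highest `primaryid`. All child
#' tables are filtered to the survivors. Attribute `n_removed` counts the
#' discarded versions.
#'
#' @param bundle A `report_bundle`.
#' @return The deduplicated bundle.
#' @export
dedup_caseid <- function(bundle) {
  demo <- bundle$demo
  ord <- order(demo$caseid,
               -num_or_neginf(demo$fda_dt),
               -num_or_neginf(demo$primaryid))
  demo2 <- demo[ord, ]
  keep_pids <- demo2$primaryid[!duplicated(demo2$caseid)]
  n_removed <- nrow(demo) - length(keep_pids)
  out <- filter_bundle(bundle, keep_pids)
  attr(out, "log") <- attr(bundle, "log")
  attr(out, "n_removed") <- n_removed
  out
}

# Sorted-set fingerprint of a child table's values per report.
set_key <- function(tbl, value_col, pids) {
  v <- norm_key(tbl[[value_col]])
  keep <- !is.na(v)
  sets <- tapply(v[keep], tbl$primaryid[keep],
                 function(x) paste(sort(unique(x)), collapse = "|"))
  out <- rep(NA_TOKEN, length(pids))
  idx <- match(pids, names(sets))
  out[!is.na(idx)] <- as.character(sets[idx[!is.na(idx)]])
  out
}

#' Deduplicate reports identical on demographic and clinical fields
#'
#' Reports identical on sex, age (value and unit), country, event date (at
#' its stored precision), the sorted reaction-term set, the sorted
#' ingredient set and the sorted indication set are treated as clones of
#' one report; the highest `primaryid` survives. Missing values compare
#' equal to each other. Intended to run after [dedup_caseid()].
#'
#' @param bundle A `report_bundle`.
#' @return The deduplicated bundle, with attribute `n_removed`.
#' @export
dedup_fieldmatch <- function(bundle) {
  demo <- bundle$demo
  pids <- demo$primaryid
  ing <- bundle$drug
  ing_val <- dplyr::coalesce(ing$ingredient, ing$drug_name)
  ing_tbl <- tibble::tibble(primaryid = ing$primaryid, v = ing_val)
  key <- paste(
    na_token(norm_key(demo$sex)),
    na_token(demo$age), na_token(norm_key(demo$age_unit)),
    na_token(norm_key(demo$country_code)),
    na_token(demo$event_dt),
    set_key(bundle$reac, "pt", pids),
    set_key(ing_tbl, "v", pids),
    set_key(bundle$indi, "indication_pt", pids),
    sep = "\r"
  )
  ord <- order(key, -num_or_neginf(pids))
  keep_pids <- pids[ord][!duplicated(key[ord])]
  n_removed <- length(pids) - length(keep_pids)
  out <- filter_bundle(bundle, keep_pids)
  attr(out, "log") <- attr(bundle, "log")
  attr(out, "n_removed") <- n_removed
  out
}

#' Remove reports whose case id is on a deleted-case list
#'
#' @param bundle A `report_bundle`.
#' @param deleted Character vector of case ids; defaults to the bundle's
#'   own deleted list.
#' @return The filtered bundle, with attribute `n_removed`.
#' @export
remove_deleted <- function(bundle, deleted = bundle$deleted) {
  keep_pids <- bundle$demo$primaryid[!(bundle$demo$caseid %in% deleted)]
  n_removed <- nrow(bundle$demo) - length(keep_pids)
  out <- filter_bundle(bundle, keep_pids)
  attr(out, "log") <- attr(bundle, "log")
  attr(out, "n_removed") <- n_removed
  out
}

#' Flag case reports under a case definition
#'
#' A report is a case iff it carries at least one drug row whose ingredient
#' matches the target with an eligible role, and no indication reported for
#' the target drug matches the exclusion sets (exact term match or
#' case-insensitive substring match on the keywords). Everything else is a
#' non-case, so cases and non-cases partition the bundle.
#'
#' @param bundle A deduplicated `report_bundle` with ingredients
#'   normalised.
#' @param cd A [case_definition()].
#' @return A tibble `(primaryid, is_case)` with counter attributes
#'   `n_excluded_role` (target reports with no eligible role) and
#'   `n_excluded_indication` (eligible-role reports removed for an excluded
#'   indication).
#' @export
flag_cases <- function(bundle, cd) {
  stopifnot(inherits(cd, "case_definition"))
  drug <- bundle$drug
  ing <- norm_key(dplyr::coalesce(drug$ingredient, drug$drug_name))
  tgt <- norm_key(cd$target_ingredient)
  trows <- which(!is.na(ing) & ing == tgt)
  if (!length(trows)) {
    warning("target ingredient '", cd$target_ingredient,
            "' absent from bundle; zero cases")
  }
  has_target <- unique(drug$primaryid[trows])
  eligible <- unique(drug$primaryid[trows][
    drug$role_code[trows] %in% cd$eligible_roles
  ])

  tkeys <- unique(paste(drug$primaryid[trows], drug$drug_seq[trows]))
  indi <- bundle$indi
  ti <- indi[paste(indi$primaryid, indi$drug_seq) %in% tkeys, ]
  ipt <- norm_key(ti$indication_pt)
  excl <- ipt %in% norm_key(cd$excluded_indication_pts)
  for (kw in cd$excluded_indication_keywords) {
    excl <- excl | grepl(tolower(kw), ipt, fixed = TRUE)
  }
  excluded_pids <- unique(ti$primaryid[excl & !is.na(ipt)])

  case_pids <- setdiff(eligible, excluded_pids)
  out <- tibble::tibble(
    primaryid = bundle$demo$primaryid,
    is_case = bundle$demo$primaryid %in% case_pids
  )
  attr(out, "n_excluded_role") <- length(setdiff(has_target, eligible))
  attr(out, "n_excluded_indication") <- length(intersect(eligible,
                                                         excluded_pids))
  out
}

#' Construct a 2x2 case/non-case contingency table
#'
#' Cell `a` counts case reports mentioning the target reaction term, `b`
#' the remaining case reports, `c` non-case reports mentioning the term and
#' `d` the remaining non-cases. Counting is report-level: a term listed
#' twice on one report counts once.
#'
#' @param a,b,c,d Non-negative counts.
#' @param pt Reaction term label.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d, pt = NA_character_) {
  if (any(c(a, b, c, d) < 0)) stop("contingency counts must be >= 0")
  structure(list(a = a, b = b, c = c, d = d, pt = pt),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table>", x$pt, ": a =", x$a, " b =", x$b,
      " c =", x$c, " d =", x$d, "\n")
  invisible(x)
}

# Report-level reaction membership joined to case flags.
pt_membership <- function(bundle, flags) {
  reac <- bundle$reac
  mem <- dplyr::distinct(
    tibble::tibble(primaryid = reac$primaryid, pt_key = norm_key(reac$pt),
                   pt = trimws(reac$pt))
  )
  mem <- mem[!is.na(mem$pt_key), ]
  mem <- dplyr::distinct(mem, .data$primaryid, .data$pt_key,
                         .keep_all = TRUE)
  dplyr::left_join(mem, flags, by = "primaryid")
}

#' Build the 2x2 table for one reaction term
#'
#' @param bundle A deduplicated `report_bundle`.
#' @param flags Case flags from [flag_cases()].
#' @param pt Reaction term (matched case-insensitively after trimming).
#' @return A [contingency_table()]. A term absent from the bundle yields
#'   `a = c = 0`.
#' @export
build_contingency <- function(bundle, flags, pt) {
  mem <- pt_membership(bundle, flags)
  key <- norm_key(pt)
  hit <- mem[mem$pt_key == key, ]
  n_cases <- sum(flags$is_case)
  n_non <- sum(!flags$is_case)
  a <- sum(hit$is_case)
  c <- sum(!hit$is_case)
  contingency_table(a, n_cases - a, c, n_non - c, pt = trimws(pt))
}

#' Build 2x2 tables for every reaction term observed among cases
#'
#' @param bundle A deduplicated `report_bundle`.
#' @param flags Case flags from [flag_cases()].
#' @param pts Optional character vector restricting the terms; default is
#'   every term observed in at least one case report.
#' @return A tibble `(pt, a, b, c, d)`, one row per term.
#' @export
build_contingency_all <- function(bundle, flags, pts = NULL) {
  mem <- pt_membership(bundle, flags)
  n_cases <- sum(flags$is_case)
  n_non <- sum(!flags$is_case)
  counts <- mem |>
    dplyr::group_by(.data$pt_key) |>
    dplyr::summarise(pt = dplyr::first(.data$pt),
                     a = sum(.data$is_case),
                     c = sum(!.data$is_case), .groups = "drop")
  if (is.null(pts)) {
    counts <- counts[counts$a > 0, ]
  } else {
    counts <- counts[counts$pt_key %in% norm_key(pts), ]
  }
  tibble::tibble(pt = counts$pt, a = counts$a, b = n_cases - counts$a,
                 c = counts$c, d = n_non - counts$c)
}
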