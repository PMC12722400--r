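#' Column-name dialect for FAERS quarterly ASCII extracts
#'
#' FAERS column spellings changed across eras; a dialect maps each canonical
#' column used by this package to the raw header spellings it accepts
#' (matched case-insensitively, first hit wins). The bundled default covers
#' the modern (post-2014) quarterly extracts plus the package's own
#' canonical names, so files written by [write_report_bundle()] round-trip.
#'
#' @return A named list of per-table column maps.
#' @export
faers_dialect <- function() {
  list(
    demo = list(
      primaryid = "primaryid", caseid = "caseid", fda_dt = "fda_dt",
      event_dt = "event_dt", sex = c("sex", "gndr_cod"), age = "age",
      age_unit = c("age_unit", "age_cod"), weight = c("weight", "wt"),
      country_code = "country_code",
      occur_country = c("occur_country", "occr_country"),
      reporter_country = "reporter_country",
      reporter_qualification = c("reporter_qualification", "occp_cod"),
      report_year = "report_year"
    ),
    drug = list(
      primaryid = "primaryid", drug_seq = "drug_seq",
      role_code = c("role_code", "role_cod"),
      drug_name = c("drug_name", "drugname"),
      ingredient = c("ingredient", "prod_ai")
    ),
    reac = list(primaryid = "primaryid", pt = "pt"),
    outc = list(
      primaryid = "primaryid",
      outcome_code = c("outcome_code", "outc_cod", "outc_code")
    ),
    ther = list(
      primaryid = "primaryid", drug_seq = c("drug_seq", "dsg_drug_seq"),
      start_dt = "start_dt", end_dt = "end_dt"
    ),
    indi = list(
      primaryid = "primaryid", drug_seq = c("drug_seq", "indi_drug_seq"),
      indication_pt = c("indication_pt", "indi_pt")
    )
  )
}

role_codes <- function() c("PS", "SS", "I", "C")
outcome_codes <- function() c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

demo_cols <- c(
  "primaryid", "caseid", "fda_dt", "event_dt", "sex", "age", "age_unit",
  "weight", "country_code", "reporter_qualification", "report_year"
)

empty_table <- function(cols) {
  out <- tibble::as_tibble(stats::setNames(
    replicate(length(cols), character(0), simplify = FALSE), cols
  ))
  out
}

#' Construct a validated report bundle
#'
#' A report bundle holds the six linked tables of a spontaneous-report
#' extract (demographics, drugs, reactions, outcomes, therapy dates,
#' indications) plus the deleted-case list. The unit of analysis is one
#' report, keyed by `primaryid`. Construction canonicalises column types,
#' restricts `role_code`/`outcome_code` to their vocabularies, drops rows
#' failing referential integrity (child rows whose `primaryid` is absent
#' from `demo`, or therapy/indication rows whose `(primaryid, drug_seq)` is
#' absent from `drug`) and records every drop in a counter log attached as
#' attribute `"log"`.
#'
#' @param demo,drug,reac,outc,ther,indi Data frames with canonical columns
#'   (see [faers_dialect()]); missing optional columns are filled with NA.
#' @param deleted Character vector of deleted case ids.
#' @return An object of class `report_bundle`.
#' @export
report_bundle <- function(demo, drug, reac, outc, ther, indi,
                          deleted = character()) {
  log <- list()
  fill <- function(tbl, cols) {
    tbl <- tibble::as_tibble(tbl)
    for (cl in setdiff(cols, names(tbl))) tbl[[cl]] <- NA_character_
    tbl[cols]
  }
  as_chr <- function(tbl, except = c("age", "weight")) {
    for (cl in names(tbl)) {
      tbl[[cl]] <- if (cl %in% except) {
        suppressWarnings(as.numeric(tbl[[cl]]))
      } else {
        x <- trimws(as.character(tbl[[cl]]))
        x[!is.na(x) & x == ""] <- NA_character_
        x
      }
    }
    tbl
  }
  demo <- as_chr(fill(demo, demo_cols))
  drug <- as_chr(fill(drug, c("primaryid", "drug_seq", "role_code",
                              "drug_name", "ingredient")))
  reac <- as_chr(fill(reac, c("primaryid", "pt")))
  outc <- as_chr(fill(outc, c("primaryid", "outcome_code")))
  ther <- as_chr(fill(ther, c("primaryid", "drug_seq", "start_dt", "end_dt")))
  indi <- as_chr(fill(indi, c("primaryid", "drug_seq", "indication_pt")))

  bad_demo <- is.na(demo$primaryid) | is.na(demo$caseid)
  log$dropped_demo_missing_ids <- sum(bad_demo)
  demo <- demo[!bad_demo, ]
  # derive report_year when absent: event year, else FDA receipt year
  yr <- function(x) {
    out <- rep(NA_character_, length(x))
    ok <- !is.na(x) & grepl("^[0-9]{4}", x)
    out[ok] <- substr(x[ok], 1, 4)
    out
  }
  demo$report_year <- dplyr::coalesce(demo$report_year, yr(demo$event_dt),
                                      yr(demo$fda_dt))

  bad_role <- !is.na(drug$role_code) & !(toupper(drug$role_code) %in% role_codes())
  log$dropped_drug_bad_role <- sum(bad_role)
  drug <- drug[!bad_role, ]
  drug$role_code <- toupper(drug$role_code)

  bad_out <- is.na(outc$outcome_code) |
    !(toupper(outc$outcome_code) %in% outcome_codes())
  log$dropped_outc_bad_code <- sum(bad_out)
  outc <- outc[!bad_out, ]
  outc$outcome_code <- toupper(outc$outcome_code)

  bad_pt <- is.na(reac$pt)
  log$dropped_reac_empty_pt <- sum(bad_pt)
  reac <- reac[!bad_pt, ]

  pids <- demo$primaryid
  ref <- function(tbl, nm) {
    bad <- !(tbl$primaryid %in% pids)
    log[[paste0("dropped_", nm, "_orphan")]] <<- sum(bad)
    tbl[!bad, ]
  }
  drug <- ref(drug, "drug"); reac <- ref(reac, "reac")
  outc <- ref(outc, "outc"); ther <- ref(ther, "ther"); indi <- ref(indi, "indi")

  dk <- paste(drug$primaryid, drug$drug_seq)
  seqref <- function(tbl, nm) {
    bad <- !(paste(tbl$primaryid, tbl$drug_seq) %in% dk)
    log[[paste0("dropped_", nm, "_no_drug")]] <<- sum(bad)
    tbl[!bad, ]
  }
  ther <- seqref(ther, "ther"); indi <- seqref(indi, "indi")

  out <- structure(
    list(demo = demo, drug = drug, reac = reac, outc = outc,
         ther = ther, indi = indi,
         deleted = unique(trimws(as.character(deleted)))),
    class = "report_bundle"
  )
  attr(out, "log") <- log
  out
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>", nrow(x$demo), "reports;",
      nrow(x$drug), "drug rows;", nrow(x$reac), "reaction rows;",
      length(x$deleted), "deleted case ids\n")
  invisible(x)
}

#' Assert the internal invariants of a report bundle
#'
#' Re-joins all child tables to check referential integrity, vocabulary
#' restrictions and non-empty reaction terms. Errors on the first violation.
#'
#' @param bundle A `report_bundle`.
#' @return The bundle, invisibly.
#' @export
validate_report_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "report_bundle"))
  pids <- bundle$demo$primaryid
  if (anyDuplicated(pids)) stop("duplicate primaryid in demo")
  for (nm in c("drug", "reac", "outc", "ther", "indi")) {
    if (!all(bundle[[nm]]$primaryid %in% pids)) {
      stop("orphan primaryid in ", nm)
    }
  }
  dk <- paste(bundle$drug$primaryid, bundle$drug$drug_seq)
  for (nm in c("ther", "indi")) {
    if (!all(paste(bundle[[nm]]$primaryid, bundle[[nm]]$drug_seq) %in% dk)) {
      stop("(primaryid, drug_seq) in ", nm, " absent from drug")
    }
  }
  if (!all(is.na(bundle$drug$role_code) |
           bundle$drug$role_code %in% role_codes())) {
    stop("invalid role_code")
  }
  if (!all(bundle$outc$outcome_code %in% outcome_codes())) {
    stop("invalid outcome_code")
  }
  if (any(is.na(bundle$reac$pt) | trimws(bundle$reac$pt) == "")) {
    stop("empty PT in reac")
  }
  invisible(bundle)
}

find_table_file <- function(directory, stem) {
  files <- list.files(directory, full.names = TRUE)
  hit <- files[grepl(paste0("^", stem), basename(files), ignore.case = TRUE) &
                 grepl("\\.(txt|tsv|csv)$", files, ignore.case = TRUE)]
  if (length(hit) == 0) return(NA_character_)
  hit[1]
}

read_dollar_table <- function(path, colmap) {
  raw <- readr::read_delim(
    path, delim = "$", col_types = readr::cols(.default = "c"),
    trim_ws = TRUE, na = c("", "NA"), show_col_types = FALSE,
    locale = readr::locale(encoding = "UTF-8"), progress = FALSE
  )
  n_malformed <- nrow(readr::problems(raw))
  if (ncol(raw) == 0) stop("unparseable header in ", path)
  lownames <- tolower(names(raw))
  out <- tibble::tibble(.rows = nrow(raw))
  for (canon in names(colmap)) {
    idx <- match(tolower(colmap[[canon]]), lownames)
    idx <- idx[!is.na(idx)]
    out[[canon]] <- if (length(idx)) raw[[idx[1]]] else NA_character_
  }
  attr(out, "n_malformed") <- n_malformed
  out
}

#' Read one quarterly FAERS-style extract
#'
#' Reads the six `$`-delimited tables (files whose names start with
#' `DEMO`, `DRUG`, `REAC`, `OUTC`, `THER`, `INDI`, case-insensitive) from a
#' directory, canonicalises column names through a dialect map, resolves the
#' country field (occurrence country when present, reporter country
#' otherwise) and assembles a validated [report_bundle()]. Rows failing
#' referential integrity or vocabulary checks are dropped and counted in
#' the run log (attribute `"log"`); a missing mandatory table is a hard
#' error naming the file stem.
#'
#' @param directory Directory containing the table files.
#' @param dialect Column dialect, see [faers_dialect()].
#' @param deleted Character vector of deleted case ids to attach (see
#'   [read_deleted_cases()]).
#' @return A `report_bundle`.
#' @export
read_faers_quarter <- function(directory, dialect = faers_dialect(),
                               deleted = character()) {
  stems <- c("demo", "drug", "reac", "outc", "ther", "indi")
  paths <- stats::setNames(
    vapply(stems, function(s) find_table_file(directory, s), character(1)),
    stems
  )
  missing <- stems[is.na(paths)]
  if (length(missing)) {
    stop("missing mandatory table file(s): ",
         paste(toupper(missing), collapse = ", "), " in ", directory)
  }
  tabs <- lapply(stems, function(s) read_dollar_table(paths[[s]], dialect[[s]]))
  names(tabs) <- stems
  n_malformed <- sum(vapply(tabs, function(t) attr(t, "n_malformed") %||% 0L,
                            numeric(1)))

  demo <- tabs$demo
  demo$country_code <- dplyr::coalesce(
    demo$country_code, demo$occur_country, demo$reporter_country
  )
  demo$occur_country <- NULL
  demo$reporter_country <- NULL

  out <- report_bundle(demo, tabs$drug, tabs$reac, tabs$outc, tabs$ther,
                       tabs$indi, deleted = deleted)
  log <- attr(out, "log")
  log$malformed_rows <- n_malformed
  attr(out, "log") <- log
  out
}

#' Write a report bundle as a FAERS-style fixture directory
#'
#' Emits the six `$`-delimited tables (`DEMO.txt`, ..., `INDI.txt`) with
#' canonical headers plus a newline-delimited `DELETED_CASES.txt`, in the
#' dialect accepted by [read_faers_quarter()], so that write-then-read is an
#' identity on canonicalised bundles.
#'
#' @param bundle A `report_bundle`.
#' @param directory Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_report_bundle <- function(bundle, directory) {
  stopifnot(inherits(bundle, "report_bundle"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory ", directory)
  }
  for (nm in c("demo", "drug", "reac", "outc", "ther", "indi")) {
    readr::write_delim(bundle[[nm]],
                       file.path(directory, paste0(toupper(nm), ".txt")),
                       delim = "$", na = "")
  }
  writeLines(bundle$deleted, file.path(directory, "DELETED_CASES.txt"))
  invisible(directory)
}

#' Parse FAERS partial dates
#'
#' FAERS dates are 4-, 6- or 8-digit strings (`YYYY`, `YYYYMM`,
#' `YYYYMMDD`). The parser is total: every input maps to exactly one
#' partial date, with anything unparseable (wrong length, out-of-range
#' month or calendar-invalid day) mapped to precision `"missing"` and
#' counted in attribute `"n_invalid"`.
#'
#' @param x Character vector of raw date strings.
#' @return A tibble with columns `year`, `month`, `day` (integer or NA) and
#'   `precision` (one of `"day"`, `"month"`, `"year"`, `"missing"`).
#' @export
#' @examples
#' parse_partial_date(c("20240315", "202403", "2024", "", "20231341"))
parse_partial_date <- function(x) {
  x <- as.character(x)
  xs <- gsub("\\s", "", x)
  xs[is.na(xs)] <- ""
  n <- nchar(xs)
  digits <- grepl("^[0-9]+$", xs)
  year <- month <- day <- rep(NA_integer_, length(xs))
  prec <- rep("missing", length(xs))

  i4 <- digits & n == 4
  year[i4] <- as.integer(xs[i4])
  prec[i4] <- "year"

  i6 <- digits & n == 6
  if (any(i6)) {
    m <- as.integer(substr(xs[i6], 5, 6))
    ok <- m >= 1 & m <= 12
    year[i6][ok] <- as.integer(substr(xs[i6], 1, 4))[ok]
    month[i6][ok] <- m[ok]
    prec[i6][ok] <- "month"
  }

  i8 <- digits & n == 8
  if (any(i8)) {
    d <- as.Date(xs[i8], format = "%Y%m%d")  # NA for calendar-invalid dates
    ok <- !is.na(d)
    year[i8][ok] <- as.integer(format(d[ok], "%Y"))
    month[i8][ok] <- as.integer(format(d[ok], "%m"))
    day[i8][ok] <- as.integer(format(d[ok], "%d"))
    prec[i8][ok] <- "day"
  }

  out <- tibble::tibble(year = year, month = month, day = day,
                        precision = prec)
  attr(out, "n_invalid") <- sum(prec == "missing" & nchar(xs) > 0)
  out
}

#' Convert day-precision partial dates to Date
#'
#' @param pd A tibble from [parse_partial_date()].
#' @return A `Date` vector; NA wherever precision is not `"day"`.
#' @export
partial_date_to_date <- function(pd) {
  out <- rep(as.Date(NA), nrow(pd))
  i <- pd$precision == "day"
  out[i] <- as.Date(sprintf("%04d-%02d-%02d", pd$year[i], pd$month[i],
                            pd$day[i]))
  out
}

#' Build an ingredient dictionary
#'
#' Maps raw (brand or verbatim) drug names to active ingredients. Keys are
#' unique after case-folding and trimming; duplicated keys keep the first
#' mapping with a warning.
#'
#' @param raw_name,ingredient Character vectors of equal length.
#' @return A tibble of class `ingredient_dictionary`.
#' @export
ingredient_dictionary <- function(raw_name, ingredient) {
  key <- norm_key(raw_name)
  ingredient <- trimws(as.character(ingredient))
  if (any(is.na(key)) || any(is.na(ingredient) | ingredient == "")) {
    stop("dictionary raw names and ingredients must be non-empty")
  }
  if (anyDuplicated(key)) {
    warning("duplicated dictionary keys after case-folding; keeping first")
    keep <- !duplicated(key)
    key <- key[keep]; raw_name <- raw_name[keep]; ingredient <- ingredient[keep]
  }
  structure(
    tibble::tibble(raw_name = trimws(as.character(raw_name)),
                   ingredient = ingredient, key = key),
    class = c("ingredient_dictionary", "tbl_df", "tbl", "data.frame")
  )
}

#' Read an ingredient dictionary from delimited text
#'
#' @param path Two-column delimited file with header `raw_name`,
#'   `ingredient`.
#' @param delim Field delimiter (default tab).
#' @return An [ingredient_dictionary()].
#' @export
read_ingredient_dictionary <- function(path, delim = "\t") {
  tbl <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = "c"),
                           trim_ws = TRUE, show_col_types = FALSE)
  if (!all(c("raw_name", "ingredient") %in% tolower(names(tbl)))) {
    names(tbl)[1:2] <- c("raw_name", "ingredient")
  } else {
    names(tbl) <- tolower(names(tbl))
  }
  ingredient_dictionary(tbl$raw_name, tbl$ingredient)
}

#' Map reported drug names to active ingredients
#'
#' Fills the `ingredient` column of a drug table from a dictionary lookup
#' on the trimmed, case-folded `drug_name`. Unmatched names are carried
#' through unchanged (an already-present ingredient is kept; otherwise the
#' verbatim name stands in) and counted. Attributes `n_mapped` and
#' `n_unmatched` record the tally.
#'
#' @param drug_table Drug table of a `report_bundle`.
#' @param dict An [ingredient_dictionary()], possibly empty.
#' @return The drug table with `ingredient` filled.
#' @export
normalize_ingredients <- function(drug_table, dict) {
  if (is.null(dict) || nrow(dict) == 0) {
    warning("empty ingredient dictionary; drug names passed through")
    attr(drug_table, "n_mapped") <- 0L
    attr(drug_table, "n_unmatched") <- nrow(drug_table)
    return(drug_table)
  }
  idx <- match(norm_key(drug_table$drug_name), dict$key)
  mapped <- !is.na(idx)
  drug_table$ingredient <- ifelse(
    mapped, dict$ingredient[idx],
    dplyr::coalesce(drug_table$ingredient, drug_table$drug_name)
  )
  attr(drug_table, "n_mapped") <- sum(mapped)
  attr(drug_table, "n_unmatched") <- sum(!mapped)
  drug_table
}

#' Read deleted-case lists
#'
#' Each file holds one case id per line; the union is returned with
#' duplicates removed. A missing file warns and contributes nothing.
#'
#' @param paths Character vector of file paths.
#' @return Character vector of unique case ids.
#' @export
read_deleted_cases <- function(paths) {
  out <- character()
  for (p in paths) {
    if (!file.exists(p)) {
      warning("deleted-case file not found: ", p)
      next
    }
    ids <- trimws(readLines(p, warn = FALSE))
    out <- c(out, ids[ids != ""])
  }
  unique(out)
}
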