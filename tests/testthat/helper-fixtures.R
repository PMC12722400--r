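# Hand-built fixtures and brute-force oracles shared across the suite.

# A ten-report universe exercised by flagging, contingency and DDI tests.
# Reports 1-5 carry the target (esketamine); 6-10 do not.
tiny_bundle <- function() {
  demo <- tibble::tibble(
    primaryid = as.character(1:10), caseid = as.character(101:110),
    fda_dt = "20230101", event_dt = "20221201",
    sex = c("F", "M", "F", "M", "F", "M", "F", "M", "F", "M"),
    age = c(30, 40, 50, 70, 25, 33, 44, 55, 66, 77), age_unit = "YR",
    weight = 70, country_code = "US", reporter_qualification = "MD",
    report_year = "2022"
  )
  drug <- tibble::tribble(
    ~primaryid, ~drug_seq, ~role_code, ~drug_name, ~ingredient,
    "1", "1", "PS", "SPRAVATO", "esketamine",
    "1", "2", "SS", "RISPERIDONE", "risperidone",
    "2", "1", "PS", "ESKETAMINE", "esketamine",
    "3", "1", "SS", "ESKETAMINE", "esketamine",
    "3", "2", "I", "RISPERIDONE", "risperidone",
    "4", "1", "C", "ESKETAMINE", "esketamine",   # concomitant only
    "5", "1", "PS", "ESKETAMINE", "esketamine",  # excluded indication
    "6", "1", "PS", "RISPERIDONE", "risperidone",
    "7", "1", "PS", "VENLAFAXINE", "venlafaxine",
    "8", "1", "C", "RISPERIDONE", "risperidone", # C never counts as B
    "9", "1", "PS", "IBUPROFEN", "ibuprofen",
    "10", "1", "PS", "METFORMIN", "metformin"
  )
  reac <- tibble::tribble(
    ~primaryid, ~pt,
    "1", "Vertigo", "1", "Nausea",
    "2", "Vertigo",
    "3", "Sedation",
    "4", "Vertigo",
    "5", "Nausea",
    "6", "Vertigo",
    "7", "Nausea",
    "8", "Vertigo",
    "9", "Headache",
    "10", "Nausea"
  )
  outc <- tibble::tibble(primaryid = c("1", "4", "6"),
                         outcome_code = c("HO", "DE", "OT"))
  ther <- tibble::tibble(primaryid = c("1", "2"), drug_seq = c("1", "1"),
                         start_dt = c("20221101", "20221115"),
                         end_dt = NA_character_)
  indi <- tibble::tibble(
    primaryid = c("1", "2", "5"), drug_seq = c("1", "1", "1"),
    indication_pt = c("Treatment resistant depression", "Major depression",
                      "Anaesthesia")
  )
  report_bundle(demo, drug, reac, outc, ther, indi)
}

tiny_cd <- function() case_definition("esketamine")

# Brute-force report-level contingency recount.
oracle_contingency <- function(bundle, flags, pt) {
  pids <- bundle$demo$primaryid
  has <- vapply(pids, function(p) {
    any(tolower(trimws(bundle$reac$pt[bundle$reac$primaryid == p])) ==
          tolower(trimws(pt)))
  }, logical(1))
  cs <- flags$is_case[match(pids, flags$primaryid)]
  c(a = sum(has & cs), b = sum(!has & cs), c = sum(has & !cs),
    d = sum(!has & !cs))
}

# Brute-force survivor set for caseid dedup: per caseid keep max fda_dt,
# ties by max primaryid.
oracle_dedup_caseid <- function(demo) {
  unlist(lapply(split(seq_len(nrow(demo)), demo$caseid), function(i) {
    d <- demo[i, ]
    fda <- suppressWarnings(as.numeric(d$fda_dt)); fda[is.na(fda)] <- -Inf
    d <- d[fda == max(fda), ]
    d$primaryid[which.max(as.numeric(d$primaryid))]
  }), use.names = FALSE)
}

# Brute-force field-match key per report.
oracle_fieldmatch_keys <- function(bundle) {
  vapply(bundle$demo$primaryid, function(p) {
    d <- bundle$demo[bundle$demo$primaryid == p, ]
    setstr <- function(x) paste(sort(unique(tolower(trimws(x[!is.na(x)])))),
                                collapse = "|")
    ing <- bundle$drug[bundle$drug$primaryid == p, ]
    paste(
      ifelse(is.na(d$sex), ".", tolower(d$sex)),
      ifelse(is.na(d$age), ".", d$age),
      ifelse(is.na(d$age_unit), ".", tolower(d$age_unit)),
      ifelse(is.na(d$country_code), ".", tolower(d$country_code)),
      ifelse(is.na(d$event_dt), ".", d$event_dt),
      setstr(bundle$reac$pt[bundle$reac$primaryid == p]),
      setstr(ifelse(is.na(ing$ingredient), ing$drug_name, ing$ingredient)),
      setstr(bundle$indi$indication_pt[bundle$indi$primaryid == p]),
      sep = "\036"
    )
  }, character(1))
}

# Brute-force DDI counting by per-report loops on small universes.
oracle_ddi_counts <- function(bundle, flags, drug_b, ae,
                              universe = "case_reports") {
  pids <- bundle$demo$primaryid
  lowdrug <- tolower(trimws(ifelse(is.na(bundle$drug$ingredient),
                                   bundle$drug$drug_name,
                                   bundle$drug$ingredient)))
  stat <- function(p) {
    rows <- bundle$drug$primaryid == p
    has_b <- any(lowdrug[rows] == tolower(drug_b) &
                   bundle$drug$role_code[rows] %in% c("PS", "SS", "I"))
    has_ae <- any(tolower(trimws(bundle$reac$pt[
      bundle$reac$primaryid == p])) == tolower(ae))
    c(case = flags$is_case[flags$primaryid == p], b = has_b, ae = has_ae)
  }
  m <- t(vapply(pids, stat, logical(3)))
  in_u <- if (universe == "case_reports") m[, "case"] else rep(TRUE, nrow(m))
  cell <- function(ae_only = FALSE, a, b) {
    sel <- m[, "case"] == a & m[, "b"] == b
    if (ae_only) sum(sel & m[, "ae"]) else sum(sel)
  }
  ddi_count_set(
    n_AB1 = sum(in_u & m[, "case"] & m[, "b"] & m[, "ae"]),
    n_A1 = sum(in_u & m[, "case"] & !m[, "b"] & m[, "ae"]),
    n_AB_plus = sum(in_u & m[, "case"] & m[, "b"]),
    n_B_plus = sum(in_u & !m[, "case"] & m[, "b"]),
    n_plusplus = sum(in_u),
    n11 = cell(TRUE, TRUE, TRUE), N11 = cell(FALSE, TRUE, TRUE),
    n10 = cell(TRUE, TRUE, FALSE), N10 = cell(FALSE, TRUE, FALSE),
    n01 = cell(TRUE, FALSE, TRUE), N01 = cell(FALSE, FALSE, TRUE),
    n00 = cell(TRUE, FALSE, FALSE), N00 = cell(FALSE, FALSE, FALSE)
  )
}

# Random small universe used for enumeration cross-checks.
random_small_bundle <- function(n, seed) {
  set.seed(seed)
  demo <- tibble::tibble(
    primaryid = as.character(seq_len(n)),
    caseid = as.character(1000 + seq_len(n)),
    fda_dt = "20230101",
    event_dt = "20221001",
    sex = sample(c("F", "M"), n, TRUE), age = sample(20:80, n, TRUE),
    age_unit = "YR", weight = 70, country_code = "US",
    reporter_qualification = "MD", report_year = "2022"
  )
  drugs <- c("esketamine", "drugb", "drugc")
  drug <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    picked <- drugs[runif(3) < c(0.5, 0.4, 0.3)]
    if (!length(picked)) picked <- "drugc"
    tibble::tibble(primaryid = as.character(i),
                   drug_seq = as.character(seq_along(picked)),
                   role_code = sample(c("PS", "SS", "I", "C"),
                                      length(picked), TRUE,
                                      prob = c(.5, .2, .1, .2)),
                   drug_name = toupper(picked), ingredient = picked)
  }))
  pts <- c("Vertigo", "Nausea", "Headache")
  reac <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    picked <- pts[runif(3) < c(0.4, 0.4, 0.3)]
    if (!length(picked)) picked <- "Headache"
    tibble::tibble(primaryid = as.character(i), pt = picked)
  }))
  report_bundle(demo, drug, reac,
                tibble::tibble(primaryid = character(),
                               outcome_code = character()),
                tibble::tibble(primaryid = character(),
                               drug_seq = character(),
                               start_dt = character(),
                               end_dt = character()),
                tibble::tibble(primaryid = character(),
                               drug_seq = character(),
                               indication_pt = character()))
}
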