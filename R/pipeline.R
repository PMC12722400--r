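#' Configure a full pipeline run
#'
#' Collects every analysis parameter in one object: input location (a
#' quarterly fixture directory or an in-memory bundle), the case
#' definition, screening and stratification settings, DDI thresholds and
#' the output directory. Can also be loaded from a YAML file holding the
#' same keys.
#'
#' @param input_dir Directory with quarterly tables (see
#'   [read_faers_quarter()]); ignored when `bundle` is given.
#' @param bundle An in-memory `report_bundle`.
#' @param output_dir Directory to write results into.
#' @param target_ingredient,eligible_roles,excluded_indication_pts,excluded_indication_keywords
#'   Case definition, see [case_definition()].
#' @param dictionary Optional [ingredient_dictionary()] or path to one.
#' @param comparator Comparator ingredient for the sensitivity analysis,
#'   or NULL to skip.
#' @param ci_level,min_reports,z Screening settings, see
#'   [screen_signals()].
#' @param stratify_sex,stratify_age,age_years_only Stratification
#'   toggles.
#' @param ddi Run the drug-drug-interaction stage.
#' @param ddi_universe,min_co_cases,ddi_exclusions,ddi_thresholds DDI
#'   settings, see [ddi_analysis()].
#' @param seed Seed echoed into the manifest and set before the run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, bundle = NULL, output_dir,
                       target_ingredient = "esketamine",
                       eligible_roles = c("PS", "SS"),
                       excluded_indication_pts = character(),
                       excluded_indication_keywords = c(
                         "anaesthesia", "anesthesia", "sedation", "pain",
                         "analgesia", "anaesthetic"
                       ),
                       dictionary = NULL, comparator = "venlafaxine",
                       ci_level = 0.95, min_reports = 5, z = NULL,
                       stratify_sex = TRUE, stratify_age = TRUE,
                       age_years_only = TRUE, ddi = TRUE,
                       ddi_universe = "case_reports", min_co_cases = 3,
                       ddi_exclusions = c("anxiety", "depression",
                                          "panic attack",
                                          "completed suicide",
                                          "suicidal ideation",
                                          "suicide attempt"),
                       ddi_thresholds = list(lift = 1, lift_strict = 2,
                                             conviction = 1, ai = 0,
                                             mi = 1, crr = 2),
                       seed = 1L) {
  if (is.null(bundle) && is.null(input_dir)) {
    stop("either input_dir or bundle must be given")
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop("input_dir does not exist: ", input_dir)
  }
  if (min_reports <= 0 || min_co_cases <= 0) {
    stop("thresholds must be positive")
  }
  structure(
    list(input_dir = input_dir, bundle = bundle, output_dir = output_dir,
         target_ingredient = target_ingredient,
         eligible_roles = eligible_roles,
         excluded_indication_pts = excluded_indication_pts,
         excluded_indication_keywords = excluded_indication_keywords,
         dictionary = dictionary, comparator = comparator,
         ci_level = ci_level, min_reports = min_reports, z = z,
         stratify_sex = stratify_sex, stratify_age = stratify_age,
         age_years_only = age_years_only, ddi = ddi,
         ddi_universe = ddi_universe, min_co_cases = min_co_cases,
         ddi_exclusions = ddi_exclusions, ddi_thresholds = ddi_thresholds,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read YAML configs")
  }
  args <- yaml::read_yaml(path)
  do.call(run_config, args)
}

pipeline_outputs <- c(
  "signals.tsv", "signals_comparator.tsv", "stratified_sex.tsv",
  "stratified_age.tsv", "tto.tsv", "seriousness.tsv", "ddi.tsv",
  "run_manifest.json"
)

#' Run the full signal-detection pipeline
#'
#' Orchestrates ingest, cleaning (caseid dedup, deleted-case removal,
#' field-match dedup, in that order), case flagging, disproportionality
#' screening, the comparator sensitivity analysis, sex/age stratified
#' relative RORs, time-to-onset and seriousness outputs and the DDI
#' screen, writing one tab-separated table per stage plus a JSON manifest
#' with the configuration echo and every cleaning counter. A failing
#' stage aborts with a stage-named error and removes partial outputs.
#'
#' @param config A [run_config()].
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character()
  emit <- function(tbl, name) {
    readr::write_tsv(tbl, file.path(out_dir, name))
    written <<- c(written, name)
  }
  stage <- "setup"
  on_fail <- function(e) {
    unlink(file.path(out_dir, written))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    set.seed(config$seed)
    manifest <- list(config = config[setdiff(names(config), "bundle")],
                     package_version =
                       as.character(utils::packageVersion("pvsignals")),
                     r_version = as.character(getRversion()))

    stage <- "ingest"
    bundle <- if (!is.null(config$bundle)) config$bundle else
      read_faers_quarter(config$input_dir)
    if (!is.null(config$dictionary)) {
      dict <- if (is.character(config$dictionary)) {
        read_ingredient_dictionary(config$dictionary)
      } else {
        config$dictionary
      }
      bundle$drug <- normalize_ingredients(bundle$drug, dict)
    }
    n_raw <- nrow(bundle$demo)

    stage <- "dedup"
    bundle <- dedup_caseid(bundle)
    n_caseid_dups <- attr(bundle, "n_removed")
    bundle <- remove_deleted(bundle)
    n_deleted <- attr(bundle, "n_removed")
    bundle <- dedup_fieldmatch(bundle)
    n_field_dups <- attr(bundle, "n_removed")
    n_analysis <- nrow(bundle$demo)

    stage <- "case_flagging"
    cd <- case_definition(config$target_ingredient, config$eligible_roles,
                          config$excluded_indication_pts,
                          config$excluded_indication_keywords)
    flags <- flag_cases(bundle, cd)

    stage <- "signals"
    tables <- build_contingency_all(bundle, flags)
    signals <- screen_signals(tables, min_reports = config$min_reports,
                              ci_level = config$ci_level, z = config$z)
    emit(signals, "signals.tsv")

    stage <- "comparator"
    comp <- if (!is.null(config$comparator)) {
      comparator_analysis(bundle, cd, config$comparator,
                          min_reports = config$min_reports,
                          ci_level = config$ci_level, z = config$z)
    } else {
      signals[0, ]
    }
    emit(comp, "signals_comparator.tsv")

    stage <- "stratified"
    strat_sex <- if (config$stratify_sex) {
      stratified_analysis(bundle, flags, "sex",
                          min_reports = config$min_reports,
                          ci_level = config$ci_level, z = config$z)
    } else NULL
    strat_age <- if (config$stratify_age) {
      stratified_analysis(bundle, flags, "age_group",
                          min_reports = config$min_reports,
                          ci_level = config$ci_level, z = config$z,
                          age_years_only = config$age_years_only)
    } else NULL
    emit(strat_sex %||% tibble::tibble(), "stratified_sex.tsv")
    emit(strat_age %||% tibble::tibble(), "stratified_age.tsv")

    stage <- "tto_outcomes"
    tto <- compute_tto(bundle, flags, cd)
    emit(tto, "tto.tsv")
    ser <- classify_serious(bundle)
    ser_cases <- ser[ser$primaryid %in% flags$primaryid[flags$is_case], ]
    emit(ser_cases, "seriousness.tsv")
    contrasts <- outcome_contrasts(bundle, flags, cd)

    stage <- "ddi"
    ddi_tbl <- if (config$ddi) {
      ddi_analysis(bundle, flags, signals, cd,
                   exclusions = config$ddi_exclusions,
                   min_co_cases = config$min_co_cases,
                   universe = config$ddi_universe,
                   thresholds = config$ddi_thresholds)
    } else {
      screen_ddi(tibble::tibble(ae = character(), drug_b = character()),
                 list())
    }
    emit(ddi_tbl, "ddi.tsv")

    stage <- "manifest"
    manifest$counters <- list(
      n_raw = n_raw, removed_caseid_dups = n_caseid_dups,
      removed_deleted = n_deleted, removed_fieldmatch_dups = n_field_dups,
      n_analysis = n_analysis, n_cases = sum(flags$is_case),
      n_noncases = sum(!flags$is_case),
      excluded_role = attr(flags, "n_excluded_role"),
      excluded_indication = attr(flags, "n_excluded_indication"),
      n_pts_tested = nrow(signals),
      tto_negative = attr(tto, "n_negative"),
      tto_unavailable = attr(tto, "n_unavailable"),
      ingest = attr(bundle, "log")
    )
    manifest$contrasts <- contrasts
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
    written <- c(written, "run_manifest.json")
  }, error = on_fail)
  invisible(out_dir)
}
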