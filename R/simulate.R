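#' Default reaction-term catalog for the simulator
#'
#' Around forty MedDRA-style preferred terms with baseline per-report
#' probabilities spanning common background reactions (nausea, headache)
#' down to rare drug-specific ones (dissociation, euphoric mood). The
#' baselines are structural, not a fit to any real database's margins.
#'
#' @return A tibble `(pt, p)`.
#' @export
default_pt_catalog <- function() {
  tibble::tribble(
    ~pt, ~p,
    "Nausea", 0.12, "Headache", 0.10, "Dizziness", 0.08,
    "Fatigue", 0.07, "Vomiting", 0.06, "Drug ineffective", 0.06,
    "Diarrhoea", 0.05, "Rash", 0.05, "Off label use", 0.04,
    "Insomnia", 0.04, "Anxiety", 0.04, "Depression", 0.03,
    "Pruritus", 0.03, "Dyspnoea", 0.03, "Malaise", 0.03,
    "Asthenia", 0.03, "Arthralgia", 0.025, "Back pain", 0.025,
    "Hypertension", 0.02, "Somnolence", 0.02, "Weight increased", 0.02,
    "Constipation", 0.015, "Dry mouth", 0.012, "Vertigo", 0.010,
    "Feeling abnormal", 0.010, "Paraesthesia", 0.010,
    "Product dose omission issue", 0.010, "Hypoaesthesia", 0.009,
    "Tremor", 0.008, "Palpitations", 0.008, "Agitation", 0.008,
    "Blood pressure increased", 0.008, "Memory impairment", 0.005,
    "Suicidal ideation", 0.004, "Hallucination", 0.002,
    "Panic attack", 0.002, "Sedation", 0.001, "Euphoric mood", 0.0005,
    "Dissociation", 0.0002
  )
}

#' Default drug catalog for the simulator
#'
#' Exposure probabilities and role-code distributions for the target drug
#' and a set of plausible psychiatric and background co-medications. The
#' target defaults to a brand name in 30% of its rows so brand-name
#' normalisation is exercised.
#'
#' @param target Target ingredient name.
#' @return A tibble `(ingredient, brand, p_exposure, p_ps, p_ss, p_i,
#'   p_c, p_brand)`.
#' @export
default_drug_catalog <- function(target = "esketamine") {
  tibble::tribble(
    ~ingredient, ~brand, ~p_exposure, ~p_ps, ~p_ss, ~p_i, ~p_c, ~p_brand,
    target, "SPRAVATO", 0.05, 0.95, 0.04, 0.00, 0.01, 0.30,
    "venlafaxine", NA, 0.040, 0.45, 0.10, 0.02, 0.43, 0,
    "sertraline", NA, 0.040, 0.40, 0.10, 0.02, 0.48, 0,
    "quetiapine", NA, 0.030, 0.40, 0.15, 0.02, 0.43, 0,
    "duloxetine", NA, 0.030, 0.40, 0.10, 0.02, 0.48, 0,
    "alprazolam", NA, 0.030, 0.25, 0.15, 0.05, 0.55, 0,
    "clonazepam", NA, 0.025, 0.25, 0.15, 0.05, 0.55, 0,
    "lorazepam", NA, 0.025, 0.25, 0.15, 0.05, 0.55, 0,
    "bupropion", NA, 0.020, 0.40, 0.12, 0.03, 0.45, 0,
    "lamotrigine", NA, 0.020, 0.35, 0.12, 0.03, 0.50, 0,
    "mirtazapine", NA, 0.020, 0.35, 0.12, 0.03, 0.50, 0,
    "risperidone", NA, 0.015, 0.40, 0.15, 0.05, 0.40, 0,
    "clonidine", NA, 0.010, 0.30, 0.15, 0.05, 0.50, 0,
    "lithium", NA, 0.010, 0.35, 0.15, 0.05, 0.45, 0,
    "paracetamol", NA, 0.080, 0.20, 0.10, 0.01, 0.69, 0,
    "ibuprofen", NA, 0.050, 0.20, 0.10, 0.01, 0.69, 0,
    "metformin", NA, 0.040, 0.25, 0.05, 0.01, 0.69, 0,
    "lisinopril", NA, 0.040, 0.25, 0.05, 0.01, 0.69, 0
  )
}

default_planted_signals <- function(target = "esketamine") {
  tibble::tribble(
    ~drug, ~pt, ~odds_multiplier,
    target, "Dissociation", 500,
    target, "Sedation", 100,
    target, "Euphoric mood", 25,
    target, "Suicidal ideation", 10,
    target, "Hallucination", 4,
    "venlafaxine", "Nausea", 2
  )
}

default_planted_interactions <- function(target = "esketamine") {
  tibble::tibble(drug_a = target, drug_b = "risperidone", pt = "Vertigo",
                 scale = "multiplicative", strength = 5)
}

#' Configure the synthetic report generator
#'
#' Defines the study conditions the generator emulates: report volume,
#' reaction and drug catalogs, planted single-drug signals (odds scale),
#' planted drug-pair interactions (risk scale, additive or
#' multiplicative), sex effect modifiers, the log-normal time-to-onset
#' model, duplicate/deleted injection rates and per-field missingness.
#' The defaults mirror a spontaneous-report case series for an intranasal
#' antidepressant: a 62/38 female/male split with 9% missing sex, ages
#' centred at 46 years with 30% missing, predominantly US reports, about
#' 60% serious reports, and TTO medians of 60 (serious) vs 2
#' (non-serious) days.
#'
#' @param n_reports Number of base reports before duplicate injection.
#' @param target Target ingredient.
#' @param pt_catalog Tibble `(pt, p)` of baseline reaction probabilities.
#' @param drug_catalog Tibble as [default_drug_catalog()].
#' @param planted_signals Tibble `(drug, pt, odds_multiplier)` or NULL.
#' @param planted_interactions Tibble `(drug_a, drug_b, pt, scale,
#'   strength)` or NULL; `scale` is `"additive"` (strength = excess risk)
#'   or `"multiplicative"` (strength = risk-ratio excess).
#' @param sex_effects Tibble `(pt, female_odds_multiplier)` or NULL.
#' @param tto_model List: `median_days` (named, serious/nonserious) and
#'   `sdlog` of the log-normal onset-time model.
#' @param p_serious Probability a report is serious.
#' @param p_excluded_indication Probability a target drug row carries an
#'   anaesthetic/pain indication (these reports must be excluded from the
#'   case series).
#' @param dup_rates Named vector: fraction of base reports cloned as
#'   same-caseid duplicates and as field-match duplicates.
#' @param deleted_rate Fraction of base case ids listed as deleted.
#' @param missingness Named list of per-field missingness rates.
#' @param seed Integer RNG seed; generation is fully reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_reports = 20000, target = "esketamine",
                       pt_catalog = default_pt_catalog(),
                       drug_catalog = default_drug_catalog(target),
                       planted_signals = default_planted_signals(target),
                       planted_interactions =
                         default_planted_interactions(target),
                       sex_effects = tibble::tibble(
                         pt = "Sedation", female_odds_multiplier = 1.3
                       ),
                       tto_model = list(
                         median_days = c(serious = 60, nonserious = 2),
                         sdlog = 1.3
                       ),
                       p_serious = 0.6,
                       p_excluded_indication = 0.02,
                       dup_rates = c(caseid = 0.02, fieldmatch = 0.01),
                       deleted_rate = 0.005,
                       missingness = list(sex = 0.09, age = 0.30,
                                          country = 0.013, event_dt = 0.10,
                                          ther_start = 0.25, weight = 0.60),
                       seed = 20140701L) {
  if (!is.numeric(n_reports) || n_reports < 1) stop("n_reports must be >= 1")
  probs <- c(pt_catalog$p, drug_catalog$p_exposure, p_serious,
             p_excluded_indication, dup_rates, deleted_rate,
             unlist(missingness))
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!is.null(planted_signals) && nrow(planted_signals) &&
      any(planted_signals$odds_multiplier <= 0)) {
    stop("planted signal strengths must be > 0")
  }
  if (!is.null(planted_interactions) && nrow(planted_interactions)) {
    if (any(planted_interactions$strength <= 0)) {
      stop("planted interaction strengths must be > 0")
    }
    if (!all(planted_interactions$scale %in%
               c("additive", "multiplicative"))) {
      stop("interaction scale must be additive or multiplicative")
    }
  }
  structure(
    list(n_reports = as.integer(n_reports), target = target,
         pt_catalog = pt_catalog, drug_catalog = drug_catalog,
         planted_signals = planted_signals,
         planted_interactions = planted_interactions,
         sex_effects = sex_effects, tto_model = tto_model,
         p_serious = p_serious,
         p_excluded_indication = p_excluded_indication,
         dup_rates = dup_rates, deleted_rate = deleted_rate,
         missingness = missingness, seed = as.integer(seed)),
    class = "sim_config"
  )
}

clamp_prob <- function(p, hi = 0.95) pmin(pmax(p, 0), hi)

# Clone all rows of a set of reports under fresh ids.
clone_reports <- function(tables, src_pids, new_pids, new_caseids,
                          fda_shift_days) {
  map_pid <- stats::setNames(new_pids, src_pids)
  out <- list()
  for (nm in c("drug", "reac", "outc", "ther", "indi")) {
    t <- tables[[nm]][tables[[nm]]$primaryid %in% src_pids, ]
    t$primaryid <- unname(map_pid[t$primaryid])
    out[[nm]] <- t
  }
  d <- tables$demo[match(src_pids, tables$demo$primaryid), ]
  d$primaryid <- new_pids
  d$caseid <- new_caseids
  fda <- as.Date(d$fda_dt, format = "%Y%m%d") + fda_shift_days
  d$fda_dt <- format(fda, "%Y%m%d")
  out$demo <- d
  out
}

#' Generate a synthetic report bundle with known ground truth
#'
#' Samples demographics, drug exposures with role codes, reaction sets
#' (per-term Bernoulli draws with odds modified by planted signals and
#' sex effects; planted drug-pair interactions override the affected
#' term's risk cell-wise on the risk scale), outcome codes, therapy and
#' event dates from the log-normal onset model, then injects same-caseid
#' duplicates (clone, later FDA receipt date), field-match duplicates
#' (clone, fresh caseid) and a deleted-case list. Generation is fully
#' vectorised and byte-reproducible given the seed.
#'
#' @param config A [sim_config()].
#' @return A list with elements `bundle` (a [report_bundle()]) and
#'   `truth` (planted effects, expected case ids, injected duplicate and
#'   deleted ids, per-report seriousness and onset days).
#' @export
simulate_reports <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_reports
  miss <- config$missingness
  dcat <- config$drug_catalog
  pcat <- config$pt_catalog

  primaryid <- as.character(100000000 + seq_len(n))
  caseid <- as.character(50000000 + seq_len(n))

  sex <- sample(c("F", "M"), n, TRUE, prob = c(0.62, 0.38))
  sex[runif(n) < miss$sex] <- NA
  age <- round(pmin(pmax(rnorm(n, 46, 16), 12), 95))
  age[runif(n) < miss$age] <- NA
  age_unit <- ifelse(is.na(age), NA_character_, "YR")
  weight <- round(rnorm(n, 78, 15), 1)
  weight[runif(n) < miss$weight] <- NA
  country <- sample(c("US", "CA", "GB", "JP", "IT"), n, TRUE,
                    prob = c(0.78, 0.06, 0.06, 0.05, 0.05))
  country[runif(n) < miss$country] <- NA
  qual <- sample(c("MD", "HP", "PH", "CN", "OT"), n, TRUE,
                 prob = c(0.32, 0.36, 0.02, 0.29, 0.01))

  # drug exposures ---------------------------------------------------------
  K <- nrow(dcat)
  expo <- matrix(runif(n * K), n, K) < matrix(rep(dcat$p_exposure, each = n),
                                              n, K)
  none <- rowSums(expo) == 0
  expo[none, which.max(dcat$p_exposure * (dcat$ingredient != config$target))] <- TRUE

  role_of <- function(k, m) {
    sample(role_codes(), m, TRUE,
           prob = c(dcat$p_ps[k], dcat$p_ss[k], dcat$p_i[k], dcat$p_c[k]))
  }
  drug_rows <- list()
  for (k in seq_len(K)) {
    idx <- which(expo[, k])
    if (!length(idx)) next
    m <- length(idx)
    brand <- !is.na(dcat$brand[k]) & runif(m) < dcat$p_brand[k]
    drug_rows[[k]] <- tibble::tibble(
      primaryid = primaryid[idx],
      role_code = role_of(k, m),
      drug_name = ifelse(brand, dcat$brand[k], toupper(dcat$ingredient[k])),
      ingredient = dcat$ingredient[k]
    )
  }
  drug <- dplyr::bind_rows(drug_rows)
  drug <- drug[order(drug$primaryid), ]
  drug <- drug |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::mutate(drug_seq = as.character(dplyr::row_number())) |>
    dplyr::ungroup()

  # reaction sets ----------------------------------------------------------
  J <- nrow(pcat)
  odds0 <- pcat$p / (1 - pcat$p)
  O <- matrix(rep(odds0, each = n), n, J)
  if (!is.null(config$planted_signals) && nrow(config$planted_signals)) {
    for (i in seq_len(nrow(config$planted_signals))) {
      ps <- config$planted_signals[i, ]
      k <- match(norm_key(ps$drug), norm_key(dcat$ingredient))
      j <- match(norm_key(ps$pt), norm_key(pcat$pt))
      if (is.na(k) || is.na(j)) next
      O[expo[, k], j] <- O[expo[, k], j] * ps$odds_multiplier
    }
  }
  if (!is.null(config$sex_effects) && nrow(config$sex_effects)) {
    # sex effects are effect modifiers of the target-drug signal: a
    # reporting effect common to cases and non-cases would cancel from the
    # stratum-specific ROR and be undetectable by design
    tgt_col <- match(norm_key(config$target), norm_key(dcat$ingredient))
    fem <- !is.na(sex) & sex == "F" & expo[, tgt_col]
    for (i in seq_len(nrow(config$sex_effects))) {
      j <- match(norm_key(config$sex_effects$pt[i]), norm_key(pcat$pt))
      if (is.na(j)) next
      O[fem, j] <- O[fem, j] * config$sex_effects$female_odds_multiplier[i]
    }
  }
  P <- O / (1 + O)
  if (!is.null(config$planted_interactions) &&
      nrow(config$planted_interactions)) {
    psig <- config$planted_signals
    mult_of <- function(drug, pt) {
      if (is.null(psig) || !nrow(psig)) return(1)
      hit <- norm_key(psig$drug) == norm_key(drug) &
        norm_key(psig$pt) == norm_key(pt)
      if (any(hit)) psig$odds_multiplier[which(hit)[1]] else 1
    }
    for (i in seq_len(nrow(config$planted_interactions))) {
      pi_ <- config$planted_interactions[i, ]
      ka <- match(norm_key(pi_$drug_a), norm_key(dcat$ingredient))
      kb <- match(norm_key(pi_$drug_b), norm_key(dcat$ingredient))
      j <- match(norm_key(pi_$pt), norm_key(pcat$pt))
      if (anyNA(c(ka, kb, j))) next
      p00 <- pcat$p[j]
      p10 <- clamp_prob(p00 * mult_of(pi_$drug_a, pi_$pt))
      p01 <- clamp_prob(p00 * mult_of(pi_$drug_b, pi_$pt))
      p11 <- if (pi_$scale == "multiplicative") {
        clamp_prob(p10 * p01 / p00 * pi_$strength)
      } else {
        clamp_prob(p10 + p01 - p00 + pi_$strength)
      }
      a <- expo[, ka]; b <- expo[, kb]
      P[a & b, j] <- p11
      P[a & !b, j] <- p10
      P[!a & b, j] <- p01
      P[!a & !b, j] <- p00
    }
  }
  Y <- matrix(runif(n * J), n, J) < P
  reac_rows <- which(Y, arr.ind = TRUE)
  reac <- tibble::tibble(primaryid = primaryid[reac_rows[, 1]],
                         pt = pcat$pt[reac_rows[, 2]])
  # reports with no drawn reaction get a neutral catch-all term so that
  # every report has at least one reaction row (kept out of the catalog so
  # catalog baselines stay calibrated)
  empty <- which(rowSums(Y) == 0)
  if (length(empty)) {
    reac <- dplyr::bind_rows(reac, tibble::tibble(
      primaryid = primaryid[empty], pt = "Unevaluable event"
    ))
  }

  # seriousness and outcome codes ------------------------------------------
  serious <- runif(n) < config$p_serious
  outc_rows <- list()
  sidx <- which(serious)
  if (length(sidx)) {
    code1 <- sample(outcome_codes(), length(sidx), TRUE,
                    prob = c(0.08, 0.05, 0.45, 0.04, 0.01, 0.02, 0.35))
    outc_rows[[1]] <- tibble::tibble(primaryid = primaryid[sidx],
                                     outcome_code = code1)
    extra <- sidx[runif(length(sidx)) < 0.25]
    if (length(extra)) {
      outc_rows[[2]] <- tibble::tibble(
        primaryid = primaryid[extra],
        outcome_code = sample(outcome_codes(), length(extra), TRUE)
      )
    }
  }
  outc <- dplyr::bind_rows(outc_rows)
  if (nrow(outc)) {
    outc <- dplyr::distinct(outc)
  } else {
    outc <- tibble::tibble(primaryid = character(), outcome_code = character())
  }

  # dates and onset --------------------------------------------------------
  event <- as.Date("2015-01-01") +
    sample.int(as.integer(as.Date("2024-09-30") - as.Date("2015-01-01")),
               n, TRUE)
  med <- config$tto_model$median_days
  tto <- round(rlnorm(n, meanlog = log(ifelse(serious, med[["serious"]],
                                              med[["nonserious"]])),
                      sdlog = config$tto_model$sdlog))
  fda <- event + sample(5:120, n, TRUE)
  event_dt <- format(event, "%Y%m%d")
  partial <- runif(n)
  event_dt[partial < 0.05] <- substr(event_dt[partial < 0.05], 1, 6)
  event_dt[partial >= 0.05 & partial < 0.07] <-
    substr(event_dt[partial >= 0.05 & partial < 0.07], 1, 4)
  event_dt[runif(n) < miss$event_dt] <- NA

  # therapy rows ------------------------------------------------------------
  tgt_k <- match(norm_key(config$target), norm_key(dcat$ingredient))
  start_date <- event - tto
  ther_src <- drug[drug$role_code %in% c("PS", "SS") |
                     runif(nrow(drug)) < 0.4, c("primaryid", "drug_seq",
                                                "ingredient")]
  ridx <- match(ther_src$primaryid, primaryid)
  is_tgt <- norm_key(ther_src$ingredient) == norm_key(dcat$ingredient[tgt_k])
  st <- dplyr::if_else(is_tgt, start_date[ridx],
                       event[ridx] - sample(1:400, nrow(ther_src), TRUE))
  en <- st + sample(1:200, nrow(ther_src), TRUE)
  keep <- runif(nrow(ther_src)) >= miss$ther_start
  ther <- tibble::tibble(
    primaryid = ther_src$primaryid[keep],
    drug_seq = ther_src$drug_seq[keep],
    start_dt = format(st[keep], "%Y%m%d"),
    end_dt = ifelse(runif(sum(keep)) < 0.5, format(en[keep], "%Y%m%d"),
                    NA_character_)
  )

  # indications -------------------------------------------------------------
  ing_key <- norm_key(drug$ingredient)
  tgt_rows <- which(ing_key == norm_key(config$target))
  excl_ind <- runif(length(tgt_rows)) < config$p_excluded_indication
  tgt_ind <- ifelse(
    excl_ind,
    sample(c("Anaesthesia", "Pain management", "Sedation"),
           length(tgt_rows), TRUE),
    sample(c("Treatment resistant depression", "Major depression",
             "Depression"), length(tgt_rows), TRUE, prob = c(0.6, 0.3, 0.1))
  )
  oth_rows <- which(ing_key != norm_key(config$target) &
                      runif(nrow(drug)) < 0.6)
  indi <- dplyr::bind_rows(
    tibble::tibble(primaryid = drug$primaryid[tgt_rows],
                   drug_seq = drug$drug_seq[tgt_rows],
                   indication_pt = tgt_ind),
    tibble::tibble(
      primaryid = drug$primaryid[oth_rows],
      drug_seq = drug$drug_seq[oth_rows],
      indication_pt = sample(c("Hypertension", "Type 2 diabetes mellitus",
                               "Depression", "Anxiety", "Insomnia"),
                             length(oth_rows), TRUE)
    )
  )

  demo <- tibble::tibble(
    primaryid = primaryid, caseid = caseid,
    fda_dt = format(fda, "%Y%m%d"), event_dt = event_dt,
    sex = sex, age = age, age_unit = age_unit, weight = weight,
    country_code = country, reporter_qualification = qual,
    report_year = NA_character_
  )
  tables <- list(demo = demo, drug = drug[, c("primaryid", "drug_seq",
                                              "role_code", "drug_name",
                                              "ingredient")],
                 reac = reac, outc = outc, ther = ther, indi = indi)

  # ground-truth case flags at base-report level ---------------------------
  tgt_excl_pids <- unique(drug$primaryid[tgt_rows][excl_ind])
  tgt_elig_pids <- unique(drug$primaryid[tgt_rows][
    drug$role_code[tgt_rows] %in% c("PS", "SS")])
  truth_case_pids <- setdiff(tgt_elig_pids, tgt_excl_pids)

  # duplicate injection -----------------------------------------------------
  n_cdup <- floor(n * config$dup_rates[["caseid"]])
  n_fdup <- floor(n * config$dup_rates[["fieldmatch"]])
  next_id <- 100000000 + n
  dup_caseid <- dup_field <- NULL
  if (n_cdup > 0) {
    src <- sample(primaryid, n_cdup)
    new_pids <- as.character(next_id + seq_len(n_cdup))
    next_id <- next_id + n_cdup
    cl <- clone_reports(tables, src, new_pids,
                        demo$caseid[match(src, primaryid)],
                        sample(10:90, n_cdup, TRUE))
    for (nm in names(tables)) tables[[nm]] <- dplyr::bind_rows(tables[[nm]],
                                                               cl[[nm]])
    dup_caseid <- tibble::tibble(original = src, clone = new_pids)
  }
  if (n_fdup > 0) {
    src <- sample(primaryid, n_fdup)
    new_pids <- as.character(next_id + seq_len(n_fdup))
    new_case <- as.character(60000000 + seq_len(n_fdup))
    cl <- clone_reports(tables, src, new_pids, new_case,
                        sample(10:90, n_fdup, TRUE))
    for (nm in names(tables)) tables[[nm]] <- dplyr::bind_rows(tables[[nm]],
                                                               cl[[nm]])
    dup_field <- tibble::tibble(original = src, clone = new_pids)
  }

  deleted <- sample(caseid, floor(n * config$deleted_rate))

  bundle <- report_bundle(tables$demo, tables$drug, tables$reac,
                          tables$outc, tables$ther, tables$indi,
                          deleted = deleted)
  truth <- list(
    config = config,
    case_pids = truth_case_pids,
    excluded_indication_pids = tgt_excl_pids,
    planted_signals = config$planted_signals,
    planted_interactions = config$planted_interactions,
    sex_effects = config$sex_effects,
    dup_caseid = dup_caseid, dup_fieldmatch = dup_field,
    deleted_caseids = deleted,
    serious = tibble::tibble(primaryid = primaryid, serious = serious),
    tto = tibble::tibble(primaryid = primaryid, tto_days = tto),
    n_base = n
  )
  list(bundle = bundle, truth = truth)
}

#' Write a simulated bundle as a fixture directory
#'
#' Convenience wrapper emitting the quarterly-dialect files via
#' [write_report_bundle()] and, when ground truth is supplied, a
#' `ground_truth.json` beside them.
#'
#' @param sim Output of [simulate_reports()], or a bare `report_bundle`.
#' @param directory Output directory.
#' @return The directory, invisibly.
#' @export
write_fixture <- function(sim, directory) {
  bundle <- if (inherits(sim, "report_bundle")) sim else sim$bundle
  write_report_bundle(bundle, directory)
  if (!inherits(sim, "report_bundle") && !is.null(sim$truth)) {
    truth <- sim$truth
    truth$config <- NULL
    jsonlite::write_json(truth, file.path(directory, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(directory)
}
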