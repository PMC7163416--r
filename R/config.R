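#' Cohort analysis configuration
#'
#' Houses every threshold of the analysis: the guideline LDL-c target, the
#' laboratory reliability cutoffs and the date from which low LDL-c values are
#' remeasured rather than discarded, the CVD-status window, the eGFR lookup
#' window and CKD threshold, the follow-up windows that separate short-term,
#' long-term and unrelated repeat measurements, the sequence-truncation
#' percentile, and the sequence-clustering parameters.
#'
#' @param ldl_target LDL-c target, mmol/L; a measurement is on target when
#'   strictly below it.
#' @param low_ldl_cutoff LDL-c below which a value is considered unreliable
#'   (mmol/L) when measured before `remeasure_date`.
#' @param high_tg_cutoff Triglyceride level above which a Friedewald-derived
#'   LDL-c is unreliable (mmol/L).
#' @param remeasure_date Date from which the laboratory remeasures low LDL-c,
#'   so low values on/after it are retained.
#' @param cvd_window_days CVD events up to this many days *after* a
#'   measurement still qualify it (captures preoperative screening).
#' @param egfr_window_days Calendar-day half-width for eGFR lookup around a
#'   measurement (the 48-hour window at day precision).
#' @param egfr_ckd_threshold eGFR below which CKD is assumed (mL/min/1.73m2).
#' @param short_min_days,short_max_days,long_max_days Follow-up windows in
#'   days: short-term is `[short_min_days, short_max_days]`, long-term is
#'   `(short_max_days, long_max_days]`, anything else is unrelated.
#' @param truncation_percentile Percentile of sequence lengths at which state
#'   sequences are truncated (nearest-rank).
#' @param transitions_on_truncated Estimate the transition matrix on truncated
#'   (`TRUE`) or untruncated (`FALSE`, default) related sequences.
#' @param n_clusters Number of sequence clusters.
#' @param indel_cost Insertion/deletion cost for optimal matching.
#' @param substitution_method `"constant"` or `"trate"` substitution costs.
#' @param substitution_constant Off-diagonal cost under `"constant"`.
#' @param bp_window_days Calendar-day half-width for blood-pressure lookup.
#' @return A validated list of class `ldl_cohort_config`.
#' @export
cohort_config <- function(ldl_target = 2.5,
                          low_ldl_cutoff = 0.8,
                          high_tg_cutoff = 8.0,
                          remeasure_date = as.Date("2017-01-24"),
                          cvd_window_days = 7L,
                          egfr_window_days = 2L,
                          egfr_ckd_threshold = 60,
                          short_min_days = 61L,
                          short_max_days = 183L,
                          long_max_days = 548L,
                          truncation_percentile = 75,
                          transitions_on_truncated = FALSE,
                          n_clusters = 4L,
                          indel_cost = 1.0,
                          substitution_method = c("constant", "trate"),
                          substitution_constant = 2.0,
                          bp_window_days = 7L) {
  substitution_method <- match.arg(substitution_method)
  cfg <- list(
    ldl_target = ldl_target,
    low_ldl_cutoff = low_ldl_cutoff,
    high_tg_cutoff = high_tg_cutoff,
    remeasure_date = as.Date(remeasure_date),
    cvd_window_days = as.integer(cvd_window_days),
    egfr_window_days = as.integer(egfr_window_days),
    egfr_ckd_threshold = egfr_ckd_threshold,
    short_min_days = as.integer(short_min_days),
    short_max_days = as.integer(short_max_days),
    long_max_days = as.integer(long_max_days),
    truncation_percentile = truncation_percentile,
    transitions_on_truncated = isTRUE(transitions_on_truncated),
    n_clusters = as.integer(n_clusters),
    indel_cost = indel_cost,
    substitution_method = substitution_method,
    substitution_constant = substitution_constant,
    bp_window_days = as.integer(bp_window_days)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "ldl_cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(
    cfg$ldl_target > 0,
    cfg$low_ldl_cutoff >= 0,
    cfg$high_tg_cutoff > 0,
    !is.na(cfg$remeasure_date),
    cfg$cvd_window_days >= 0,
    cfg$short_min_days > 0,
    cfg$short_min_days <= cfg$short_max_days,
    cfg$short_max_days < cfg$long_max_days,
    cfg$truncation_percentile > 0, cfg$truncation_percentile <= 100,
    cfg$n_clusters >= 2,
    cfg$indel_cost > 0,
    cfg$substitution_constant >= 0
  )
  invisible(cfg)
}

#' Read a cohort configuration from YAML
#'
#' Any subset of [cohort_config()]'s arguments may appear in the file;
#' unnamed thresholds keep their defaults.
#'
#' @param path YAML file path.
#' @return `ldl_cohort_config` object.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(cohort_config))
  extra <- setdiff(names(raw), allowed)
  if (length(extra) > 0) {
    stop("Unknown config keys: ", paste(extra, collapse = ", "), call. = FALSE)
  }
  do.call(cohort_config, raw)
}

#' Default statin equivalence table
#'
#' Potency anchors expressed as the daily dose (mg) equal in LDL-c-lowering
#' effect to atorvastatin 20 mg. Equivalent dose of a prescription is
#' `daily_dose_mg / dose_mg_equal_to_atorva20`. The table is shipped as an
#' editable CSV (`inst/extdata/statin_equivalence.csv`).
#'
#' @param path Optional path to a replacement CSV with columns
#'   `statin_type,dose_mg_equal_to_atorva20`.
#' @return Tibble with columns `statin_type`, `dose_mg_equal_to_atorva20`.
#' @export
statin_equivalence_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "statin_equivalence.csv",
                        package = "ldltraj", mustWork = TRUE)
  }
  tab <- readr::read_csv(path, col_types = readr::cols(
    statin_type = readr::col_character(),
    dose_mg_equal_to_atorva20 = readr::col_double()
  ), progress = FALSE)
  stopifnot(all(tab$dose_mg_equal_to_atorva20 > 0),
            !anyDuplicated(tab$statin_type))
  tab
}

#' Diagnosis/billing code map
#'
#' Maps local diagnosis, intervention and billing codes to the analysis
#' categories (CHD, STROKE, PAD, AAA, DIABETES, CKD, DIALYSIS). Real coding
#' systems differ per center, so the map is an editable CSV
#' (`inst/extdata/cvd_code_map.csv`); the shipped one covers the synthetic
#' generator's codes.
#'
#' @param path Optional path to a replacement CSV with columns
#'   `code,category`.
#' @return Tibble with columns `code`, `category`.
#' @export
cvd_code_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cvd_code_map.csv",
                        package = "ldltraj", mustWork = TRUE)
  }
  map <- readr::read_csv(path, col_types = readr::cols(
    code = readr::col_character(),
    category = readr::col_character()
  ), progress = FALSE)
  bad <- setdiff(map$category, diagnosis_categories())
  if (length(bad) > 0) {
    stop("Unknown categories in code map: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(map$code)) {
    stop("Code map assigns some code to more than one category",
         call. = FALSE)
  }
  map
}

diagnosis_categories <- function() {
  c("CHD", "STROKE", "PAD", "AAA", "DIABETES", "CKD", "DIALYSIS")
}

cvd_categories <- function() c("CHD", "STROKE", "PAD", "AAA")
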