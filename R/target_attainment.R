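#' Split patients by measurement repetition
#'
#' Partitions the cohort into patients with exactly one retained CVD
#' measurement and patients with two or more.
#'
#' @param contexts Measurement contexts ([build_contexts()]).
#' @return List with `single` and `repeated` character vectors of patient ids
#'   and a `counts` element.
#' @export
split_by_repetition <- function(contexts) {
  n <- dplyr::count(contexts, .data$patient_id)
  single <- n$patient_id[n$n == 1]
  repeated <- n$patient_id[n$n >= 2]
  list(single = single, repeated = repeated,
       counts = c(single = length(single), repeated = length(repeated)))
}

#' Target-attainment prevalence
#'
#' Proportion of on-target measurements (or first measurements, see
#' `first_only`), overall or grouped by calendar year or repetition stratum.
#' Numerator and denominator are always reported.
#'
#' @param contexts Measurement contexts.
#' @param grouping `"overall"`, `"per_year"` or `"per_stratum"`.
#' @param config [cohort_config()].
#' @param first_only Use only each patient's first measurement.
#' @return Tibble with group column(s), `n_on_target`, `n_total`,
#'   `prevalence`.
#' @export
attainment_prevalence <- function(contexts,
                                  grouping = c("overall", "per_year",
                                               "per_stratum"),
                                  config = cohort_config(),
                                  first_only = FALSE) {
  grouping <- match.arg(grouping)
  df <- contexts
  if (first_only) df <- first_measurements(df)
  if (nrow(df) == 0) stop("attainment_prevalence(): empty input",
                          call. = FALSE)
  df$on_target <- df$ldl < config$ldl_target
  df <- switch(grouping,
    overall = dplyr::mutate(df, group = "overall"),
    per_year = dplyr::mutate(df, group = format(.data$date, "%Y")),
    per_stratum = {
      strata <- split_by_repetition(contexts)
      dplyr::mutate(df, group = dplyr::if_else(
        .data$patient_id %in% strata$repeated, "repeated", "single"))
    }
  )
  df |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_on_target = sum(.data$on_target),
                     n_total = dplyr::n(),
                     prevalence = mean(.data$on_target), .groups = "drop") |>
    dplyr::arrange(.data$group)
}

# earliest retained measurement per patient; date ties broken by preferring
# a directly measured LDL-c over a derived one
first_measurements <- function(contexts) {
  contexts |>
    dplyr::arrange(.data$patient_id, .data$date,
                   .data$ldl_source != "measured") |>
    dplyr::distinct(.data$patient_id, .keep_all = TRUE)
}

#' Baseline characteristics table
#'
#' Per repetition stratum at the first measurement: n (%) for binary traits,
#' mean (SD) for age, median (IQR) for LDL-c. SD is reported as `NA` in
#' single-patient strata.
#'
#' @param contexts Measurement contexts.
#' @param config [cohort_config()].
#' @return Tibble, one row per (stratum, characteristic) with `stat_type`,
#'   `value1` (n / mean / median) and `value2` (% / SD / IQR bounds encoded
#'   as `q1;q3`).
#' @export
baseline_table <- function(contexts, config = cohort_config()) {
  firsts <- first_measurements(contexts)
  strata <- split_by_repetition(contexts)
  firsts$stratum <- dplyr::if_else(firsts$patient_id %in% strata$repeated,
                                   "repeated", "single")
  binify <- function(x) mean(x, na.rm = TRUE)
  firsts |>
    dplyr::group_by(.data$stratum) |>
    dplyr::group_modify(function(d, key) {
      n <- nrow(d)
      bin_row <- function(chr, x) {
        x <- x[!is.na(x)]
        tibble::tibble(characteristic = chr, stat_type = "n_pct",
                       value1 = sum(x), value2 = 100 * mean(x))
      }
      dplyr::bind_rows(
        tibble::tibble(characteristic = "n_patients", stat_type = "count",
                       value1 = n, value2 = NA_real_),
        bin_row("women", d$sex == "female"),
        tibble::tibble(characteristic = "age_years", stat_type = "mean_sd",
                       value1 = mean(d$age_years),
                       value2 = if (n > 1) stats::sd(d$age_years) else
                         NA_real_),
        tibble::tibble(characteristic = "ldl_mmol_l",
                       stat_type = "median_iqr",
                       value1 = stats::median(d$ldl),
                       value2 = NA_real_,
                       extra = paste(stats::quantile(d$ldl, c(.25, .75)),
                                     collapse = ";")),
        bin_row("smoking_current", d$smoking_current),
        bin_row("diabetes", d$diabetes),
        bin_row("hypertension", d$hypertension),
        bin_row("ckd", d$ckd),
        bin_row("statin", d$med_statin),
        bin_row("other_lipid_lowering", d$med_other_lipid_lowering),
        bin_row("bp_lowering", d$med_bp_lowering),
        bin_row("glucose_lowering", d$med_glucose_lowering),
        bin_row("antithrombotic", d$med_antithrombotic)
      )
    }) |>
    dplyr::ungroup()
}

#' Logistic model for off-target status at first measurement
#'
#' Outcome: LDL-c not on target at the patient's first retained CVD
#' measurement. Covariates: age (per year), sex (women vs men), diabetes,
#' hypertension, CKD, statin use, antithrombotic use, current smoking, and
#' having repeated measurements. Complete-case maximum-likelihood fit with
#' Wald 95\% confidence intervals.
#'
#' @param contexts Measurement contexts.
#' @param config [cohort_config()].
#' @return Odds-ratio tibble (`term`, `or`, `ci_lower`, `ci_upper`, `n`) with
#'   the fitted `glm` as attribute `fit`.
#' @export
offtarget_logistic <- function(contexts, config = cohort_config()) {
  strata <- split_by_repetition(contexts)
  df <- first_measurements(contexts) |>
    dplyr::transmute(
      off_target = .data$ldl >= config$ldl_target,
      age = .data$age_years,
      women = .data$sex == "female",
      diabetes = .data$diabetes,
      hypertension = .data$hypertension,
      ckd = .data$ckd,
      statin = .data$med_statin,
      antithrombotic = .data$med_antithrombotic,
      smoking = .data$smoking_current,
      repeated = .data$patient_id %in% strata$repeated
    ) |>
    stats::na.omit()
  if (length(unique(df$off_target)) < 2) {
    stop("offtarget_logistic(): outcome has an empty class", call. = FALSE)
  }
  fit <- stats::glm(off_target ~ age + women + diabetes + hypertension +
                      ckd + statin + antithrombotic + smoking + repeated,
                    family = stats::binomial(), data = df)
  if (!fit$converged) {
    stop("offtarget_logistic(): fit did not converge (possible separation)",
         call. = FALSE)
  }
  out <- wald_or_table(fit)
  attr(out, "fit") <- fit
  out
}

#' LDL-c distance-from-target histogram data
#'
#' Counts per LDL-c state, per repetition stratum, at the first measurement;
#' the data behind the distance-from-target distribution figure.
#'
#' @param contexts Measurement contexts.
#' @param config [cohort_config()].
#' @return Tibble with `stratum`, `state`, `n`, `proportion`.
#' @export
state_histogram <- function(contexts, config = cohort_config()) {
  strata <- split_by_repetition(contexts)
  first_measurements(contexts) |>
    dplyr::mutate(
      stratum = dplyr::if_else(.data$patient_id %in% strata$repeated,
                               "repeated", "single"),
      state = ldl_state(.data$ldl, config$ldl_target)
    ) |>
    dplyr::count(.data$stratum, .data$state, .drop = FALSE, name = "n") |>
    dplyr::group_by(.data$stratum) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}
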