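#' Classify a state transition as favorable or unfavorable
#'
#' Favorable change: the LDL-c decreases to, or remains on, target — i.e. the
#' next measurement is on target. Unfavorable: an increase, a decrease that
#' is still off target, or stable off-target LDL-c — i.e. any next state
#' other than on target. Read at the category level, these three unfavorable
#' clauses are exactly the complement of "next state on target".
#'
#' @param prev_state,next_state State labels (vectors).
#' @return Factor with levels `FAVORABLE`, `UNFAVORABLE`.
#' @export
classify_change <- function(prev_state, next_state) {
  prev <- as.character(prev_state)
  nxt <- as.character(next_state)
  ok <- c(prev, nxt) %in% ldl_state_levels()
  if (!all(ok)) stop("classify_change(): invalid state label", call. = FALSE)
  factor(ifelse(nxt == "ON_TARGET", "FAVORABLE", "UNFAVORABLE"),
         levels = c("FAVORABLE", "UNFAVORABLE"))
}

statin_change_levels <- function() {
  c("SAME_DOSE_SAME_TYPE", "SAME_DOSE_DIFF_TYPE", "HIGHER_DOSE_SAME_TYPE",
    "LOWER_DOSE_SAME_TYPE", "HIGHER_DOSE_DIFF_TYPE", "LOWER_DOSE_DIFF_TYPE")
}

#' Classify a statin change between two measurements
#'
#' Type compared by statin name; dose compared in atorvastatin-20 equivalents
#' (equality within 1e-9). A missing statin at either measurement, or a type
#' absent from the equivalence table, makes the pair not evaluable (`NA`),
#' mirroring the reduced-n statin-change analysis; starts and stops are
#' therefore not forced into the six categories.
#'
#' @param prev_type,next_type Statin names (vectors; `NA` for no statin).
#' @param prev_dose,next_dose Daily doses in mg.
#' @param equivalence Equivalence table ([statin_equivalence_table()]).
#' @return Factor over [statin_change_levels()]; `NA` where not evaluable.
#' @export
classify_statin_change <- function(prev_type, next_type, prev_dose, next_dose,
                                   equivalence = statin_equivalence_table()) {
  prev_eq <- suppressWarnings(
    statin_equivalent_dose(prev_type, prev_dose, equivalence))
  next_eq <- suppressWarnings(
    statin_equivalent_dose(next_type, next_dose, equivalence))
  same_type <- prev_type == next_type
  ddiff <- next_eq - prev_eq
  out <- dplyr::case_when(
    is.na(prev_eq) | is.na(next_eq) ~ NA_character_,
    abs(ddiff) <= 1e-9 & same_type ~ "SAME_DOSE_SAME_TYPE",
    abs(ddiff) <= 1e-9 ~ "SAME_DOSE_DIFF_TYPE",
    ddiff > 0 & same_type ~ "HIGHER_DOSE_SAME_TYPE",
    ddiff < 0 & same_type ~ "LOWER_DOSE_SAME_TYPE",
    ddiff > 0 ~ "HIGHER_DOSE_DIFF_TYPE",
    TRUE ~ "LOWER_DOSE_DIFF_TYPE"
  )
  factor(out, levels = statin_change_levels())
}

#' Build measurement-pair table for change analysis
#'
#' Every consecutive pair of a patient's linked sequence, with the change
#' label, follow-up type, measurement index, the statin at each end (most
#' recent prescription on/before each measurement date) and the statin-change
#' category.
#'
#' @param sequences Long-format sequences ([link_measurements()]).
#' @param contexts Measurement contexts (covariates and statin columns).
#' @param equivalence Statin equivalence table.
#' @return Tibble of pairs; attribute `n_not_evaluable` counts pairs without
#'   an evaluable statin change.
#' @export
change_pairs <- function(sequences, contexts,
                         equivalence = statin_equivalence_table()) {
  seq2 <- sequences |>
    dplyr::arrange(.data$patient_id, .data$index) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(next_state = dplyr::lead(.data$state),
                  next_date = dplyr::lead(.data$date),
                  next_fu = dplyr::lead(.data$follow_up_type)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$next_state))
  ctx_cols <- contexts |>
    dplyr::select("patient_id", "date", "age_years", "sex", "diabetes",
                  "hypertension", "ckd", "smoking_current",
                  "med_antithrombotic", "statin_type", "statin_dose_mg")
  pairs <- seq2 |>
    dplyr::left_join(ctx_cols, by = c("patient_id", "date")) |>
    dplyr::left_join(
      dplyr::select(ctx_cols, "patient_id", next_date = "date",
                    next_statin_type = "statin_type",
                    next_statin_dose_mg = "statin_dose_mg"),
      by = c("patient_id", "next_date")) |>
    dplyr::mutate(
      change = classify_change(.data$state, .data$next_state),
      statin_change = classify_statin_change(
        .data$statin_type, .data$next_statin_type,
        .data$statin_dose_mg, .data$next_statin_dose_mg, equivalence),
      pair_index = .data$index,
      follow_up_type = .data$next_fu
    ) |>
    dplyr::select("patient_id", "pair_index", "date", "next_date",
                  prev_state = "state", "next_state", "change",
                  "follow_up_type", "age_years", "sex", "diabetes",
                  "hypertension", "ckd", "smoking_current",
                  "med_antithrombotic", "statin_change")
  attr(pairs, "n_not_evaluable") <- sum(is.na(pairs$statin_change))
  pairs
}

#' Logistic model for LDL-c deterioration
#'
#' Outcome: unfavorable category change over a measurement pair. Covariates:
#' age, sex (women vs men), diabetes, hypertension, current smoking,
#' antithrombotic use, statin change (reference: same dose, same type),
#' measurement index, and follow-up type (reference: short-term).
#' Complete-case fit on evaluable pairs (statin present and mapped at both
#' ends); Wald 95\% confidence intervals.
#'
#' @param pairs Pair table ([change_pairs()]) or any tibble with the model
#'   columns (`change`, `age_years`, `sex`, `diabetes`, `hypertension`,
#'   `smoking_current`, `med_antithrombotic`, `statin_change`, `pair_index`,
#'   `follow_up_type`).
#' @return Odds-ratio tibble with the fitted `glm` as attribute `fit`.
#' @export
deterioration_logistic <- function(pairs) {
  df <- pairs |>
    dplyr::transmute(
      unfavorable = .data$change == "UNFAVORABLE",
      age = .data$age_years,
      women = .data$sex == "female",
      diabetes = .data$diabetes,
      hypertension = .data$hypertension,
      smoking = .data$smoking_current,
      antithrombotic = .data$med_antithrombotic,
      statin_change = factor(.data$statin_change,
                             levels = statin_change_levels()),
      measurement_index = .data$pair_index,
      follow_up = factor(as.character(.data$follow_up_type),
                         levels = c("SHORT", "LONG"))
    ) |>
    stats::na.omit()
  if (nrow(df) == 0 || length(unique(df$unfavorable)) < 2) {
    stop("deterioration_logistic(): outcome has an empty class",
         call. = FALSE)
  }
  if (sum(df$statin_change == "SAME_DOSE_SAME_TYPE") == 0) {
    stop("deterioration_logistic(): reference statin-change level is empty",
         call. = FALSE)
  }
  df$statin_change <- droplevels(df$statin_change)
  fit <- stats::glm(unfavorable ~ age + women + diabetes + hypertension +
                      smoking + antithrombotic + statin_change +
                      measurement_index + follow_up,
                    family = stats::binomial(), data = df)
  if (!fit$converged) {
    stop("deterioration_logistic(): fit did not converge ",
         "(possible separation)", call. = FALSE)
  }
  out <- wald_or_table(fit)
  attr(out, "fit") <- fit
  out
}
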