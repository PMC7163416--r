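#' Friedewald LDL-c derivation
#'
#' LDL-c = TC - HDL - TG/2.2, all in mmol/L. Vectorized; any missing input
#' yields `NA` (derivation not possible). The result may be negative or
#' unreliable at high triglycerides; filtering is the caller's job
#' ([apply_reliability_filter()]).
#'
#' @param tc,hdl,tg Total cholesterol, HDL cholesterol and triglycerides
#'   (mmol/L), non-negative.
#' @return Derived LDL-c (mmol/L), `NA` where any input is missing.
#' @examples
#' friedewald_ldl(5.0, 1.0, 2.2) # 3.0
#' @export
friedewald_ldl <- function(tc, hdl, tg) {
  if (any(c(tc, hdl, tg) < 0, na.rm = TRUE)) {
    stop("friedewald_ldl(): negative lipid value", call. = FALSE)
  }
  tc - hdl - tg / 2.2
}

#' Assemble lipid panels from long-format labs
#'
#' Groups lab rows by (patient_id, date). A date yields a panel when it has a
#' direct LDL-c measurement, or all of TC, HDL and TG (LDL-c then derived by
#' [friedewald_ldl()]). When both exist, the direct value is preferred. Dates
#' with insufficient analytes yield no panel and are counted.
#'
#' @param labs Validated labs table.
#' @return Tibble of panels: `patient_id`, `date`, `tc`, `hdl`, `tg`, `ldl`,
#'   `ldl_source` (`"measured"`/`"friedewald"`), with attribute
#'   `n_incomplete` (patient-dates with lipids but no derivable LDL-c).
#' @export
assemble_panels <- function(labs) {
  lipids <- dplyr::filter(labs, .data$analyte != "eGFR")
  if (nrow(lipids) == 0) {
    out <- tibble::tibble(patient_id = character(), date = as.Date(character()),
                          tc = double(), hdl = double(), tg = double(),
                          ldl = double(), ldl_source = character())
    attr(out, "n_incomplete") <- 0L
    return(out)
  }
  wide <- lipids |>
    dplyr::group_by(.data$patient_id, .data$date, .data$analyte) |>
    dplyr::summarise(value = dplyr::first(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "analyte", values_from = "value")
  for (a in c("TC", "HDL", "TG", "LDL_direct")) {
    if (!a %in% names(wide)) wide[[a]] <- NA_real_
  }
  wide <- wide |>
    dplyr::mutate(
      has_full = !is.na(.data$TC) & !is.na(.data$HDL) & !is.na(.data$TG),
      ldl_source = dplyr::case_when(
        !is.na(.data$LDL_direct) ~ "measured",
        .data$has_full ~ "friedewald",
        TRUE ~ NA_character_
      ),
      ldl = dplyr::if_else(.data$ldl_source == "measured", .data$LDL_direct,
                           friedewald_ldl(.data$TC, .data$HDL, .data$TG))
    )
  n_incomplete <- sum(is.na(wide$ldl_source))
  out <- wide |>
    dplyr::filter(!is.na(.data$ldl_source)) |>
    dplyr::transmute(
      patient_id = .data$patient_id, date = .data$date,
      tc = .data$TC, hdl = .data$HDL, tg = .data$TG,
      ldl = .data$ldl, ldl_source = .data$ldl_source
    ) |>
    dplyr::arrange(.data$patient_id, .data$date)
  attr(out, "n_incomplete") <- n_incomplete
  out
}

#' Laboratory reliability filter
#'
#' A panel is excluded when its LDL-c is below `low_ldl_cutoff` and dated
#' before `remeasure_date` (the laboratory then derived all LDL-c by
#' Friedewald, unreliable at low values; from the remeasure date onward low
#' values are manually remeasured and therefore retained), or when it is
#' Friedewald-derived with triglycerides above `high_tg_cutoff`. Each
#' excluded panel carries exactly one `exclusion_reason`
#' (`"low_ldl_pre2017"` takes precedence over `"high_tg"`).
#'
#' @param panels Panels from [assemble_panels()].
#' @param config [cohort_config()].
#' @return List with `retained` and `excluded` tibbles; `excluded` gains an
#'   `exclusion_reason` column. Retained plus excluded equal the input.
#' @export
apply_reliability_filter <- function(panels, config = cohort_config()) {
  low <- panels$ldl < config$low_ldl_cutoff &
    panels$date < config$remeasure_date
  high_tg <- panels$ldl_source == "friedewald" &
    !is.na(panels$tg) & panels$tg > config$high_tg_cutoff
  reason <- dplyr::case_when(low ~ "low_ldl_pre2017",
                             high_tg ~ "high_tg",
                             TRUE ~ NA_character_)
  excluded <- panels[!is.na(reason), , drop = FALSE]
  excluded$exclusion_reason <- reason[!is.na(reason)]
  list(retained = panels[is.na(reason), , drop = FALSE], excluded = excluded)
}

#' CVD status at a measurement date
#'
#' A measurement qualifies as taken in established CVD when the patient has a
#' CHD, stroke, peripheral-artery-disease or abdominal-aortic-aneurysm event
#' dated no later than `cvd_window_days` after the measurement. The one-week
#' look-ahead captures measurements taken as part of preoperative screening.
#'
#' @param patient_id Patient identifier (scalar).
#' @param date Measurement date.
#' @param diagnoses Validated diagnoses table.
#' @param config [cohort_config()].
#' @return List with `cvd` (logical) and `categories` (character vector).
#' @export
cvd_status_at <- function(patient_id, date, diagnoses,
                          config = cohort_config()) {
  ev <- diagnoses[diagnoses$patient_id == patient_id &
                    diagnoses$category %in% cvd_categories() &
                    diagnoses$date <= date + config$cvd_window_days, ,
                  drop = FALSE]
  list(cvd = nrow(ev) > 0, categories = sort(unique(ev$category)))
}

#' Classify an ATC code into a medication class
#'
#' A10 glucose lowering; B01 and B02A antithrombotic; C10AA statin; other C10
#' other lipid lowering; C02/C03/C07/C08/C09 blood pressure lowering;
#' anything else `NA`.
#'
#' @param atc_code Character vector of ATC codes.
#' @return Character vector of classes (`"glucose_lowering"`,
#'   `"antithrombotic"`, `"statin"`, `"other_lipid_lowering"`,
#'   `"bp_lowering"`) or `NA`.
#' @export
classify_medication <- function(atc_code) {
  stopifnot(is.character(atc_code), all(nzchar(atc_code)))
  dplyr::case_when(
    startsWith(atc_code, "A10") ~ "glucose_lowering",
    startsWith(atc_code, "B01") | startsWith(atc_code, "B02A") ~
      "antithrombotic",
    startsWith(atc_code, "C10AA") ~ "statin",
    startsWith(atc_code, "C10") ~ "other_lipid_lowering",
    startsWith(atc_code, "C02") | startsWith(atc_code, "C03") |
      startsWith(atc_code, "C07") | startsWith(atc_code, "C08") |
      startsWith(atc_code, "C09") ~ "bp_lowering",
    TRUE ~ NA_character_
  )
}

#' Hypertension at a measurement date
#'
#' True when the nearest blood pressure within `bp_window_days` exceeds
#' 140/90 mmHg (systolic > 140 or diastolic > 90), or any blood
#' pressure-lowering prescription was registered on or before the date.
#'
#' @param patient_id Patient identifier (scalar).
#' @param date Measurement date.
#' @param bp Blood pressure table (may be `NULL`).
#' @param prescriptions Prescriptions table.
#' @param config [cohort_config()].
#' @return Logical scalar.
#' @export
hypertension_at <- function(patient_id, date, bp, prescriptions,
                            config = cohort_config()) {
  high_bp <- FALSE
  if (!is.null(bp) && nrow(bp) > 0) {
    cand <- bp[bp$patient_id == patient_id &
                 abs(as.integer(bp$date - date)) <= config$bp_window_days, ,
               drop = FALSE]
    if (nrow(cand) > 0) {
      nearest <- cand[which.min(abs(as.integer(cand$date - date))), ]
      high_bp <- nearest$systolic > 140 || nearest$diastolic > 90
    }
  }
  rx <- prescriptions[prescriptions$patient_id == patient_id &
                        prescriptions$registration_date <= date, ,
                      drop = FALSE]
  on_bp_med <- any(classify_medication(rx$atc_code) == "bp_lowering",
                   na.rm = TRUE)
  isTRUE(high_bp) || on_bp_med
}

#' Chronic kidney disease at a measurement date
#'
#' True when a CKD or dialysis event is dated on/before the measurement, or
#' any eGFR within `egfr_window_days` calendar days falls below
#' `egfr_ckd_threshold`.
#'
#' @param patient_id Patient identifier (scalar).
#' @param date Measurement date.
#' @param diagnoses Diagnoses table.
#' @param labs Labs table (eGFR rows used).
#' @param config [cohort_config()].
#' @return Logical scalar.
#' @export
ckd_at <- function(patient_id, date, diagnoses, labs,
                   config = cohort_config()) {
  code <- any(diagnoses$patient_id == patient_id &
                diagnoses$category %in% c("CKD", "DIALYSIS") &
                diagnoses$date <= date)
  egfr <- labs[labs$patient_id == patient_id & labs$analyte == "eGFR" &
                 abs(as.integer(labs$date - date)) <= config$egfr_window_days,
               , drop = FALSE]
  code || any(egfr$value < config$egfr_ckd_threshold)
}

#' Statin dose in atorvastatin-20 equivalents
#'
#' Linear potency conversion: `daily_dose_mg / dose_mg_equal_to_atorva20` for
#' the statin type, so atorvastatin 20 mg is 1.0 by construction.
#'
#' @param statin_type Character vector of statin names (lower case).
#' @param daily_dose_mg Positive daily doses (mg).
#' @param equivalence Equivalence table ([statin_equivalence_table()]).
#' @return Numeric vector of equivalents; `NA` with a warning for statin
#'   types absent from the table (callers exclude and count these).
#' @export
statin_equivalent_dose <- function(statin_type, daily_dose_mg,
                                   equivalence = statin_equivalence_table()) {
  stopifnot(all(daily_dose_mg > 0, na.rm = TRUE))
  anchor <- equivalence$dose_mg_equal_to_atorva20[
    match(statin_type, equivalence$statin_type)]
  if (anyNA(anchor)) {
    warning("unmapped statin type(s): ",
            paste(unique(statin_type[is.na(anchor)]), collapse = ", "),
            call. = FALSE)
  }
  daily_dose_mg / anchor
}

# most recent statin prescription on/before each measurement date;
# vectorized over a (patient_id, date) frame
statin_at_measurements <- function(frame, prescriptions, equivalence) {
  statins <- prescriptions |>
    dplyr::filter(startsWith(.data$atc_code, "C10AA")) |>
    dplyr::transmute(patient_id = .data$patient_id,
                     rx_date = .data$registration_date,
                     statin_type = tolower(.data$drug_name),
                     daily_dose_mg = .data$daily_dose_mg)
  if (nrow(statins) == 0) {
    return(tibble::tibble(statin_type = rep(NA_character_, nrow(frame)),
                          statin_dose_mg = NA_real_,
                          statin_equivalents = NA_real_))
  }
  hit <- frame |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::left_join(statins, by = "patient_id",
                     relationship = "many-to-many") |>
    dplyr::filter(.data$rx_date <= .data$date) |>
    dplyr::group_by(.data$.row) |>
    dplyr::slice_max(.data$rx_date, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  out <- tibble::tibble(statin_type = rep(NA_character_, nrow(frame)),
                        statin_dose_mg = NA_real_,
                        statin_equivalents = NA_real_)
  out$statin_type[hit$.row] <- hit$statin_type
  out$statin_dose_mg[hit$.row] <- hit$daily_dose_mg
  out$statin_equivalents[hit$.row] <-
    suppressWarnings(statin_equivalent_dose(hit$statin_type,
                                            hit$daily_dose_mg, equivalence))
  out
}

# medication class flags at measurement dates (prescription on/before date)
med_flags_at_measurements <- function(frame, prescriptions) {
  rx <- prescriptions |>
    dplyr::mutate(med_class = classify_medication(.data$atc_code)) |>
    dplyr::filter(!is.na(.data$med_class))
  classes <- c("statin", "other_lipid_lowering", "bp_lowering",
               "glucose_lowering", "antithrombotic")
  out <- matrix(FALSE, nrow(frame), length(classes),
                dimnames = list(NULL, paste0("med_", classes)))
  if (nrow(rx) > 0) {
    joined <- frame |>
      dplyr::mutate(.row = dplyr::row_number()) |>
      dplyr::left_join(rx, by = "patient_id",
                       relationship = "many-to-many") |>
      dplyr::filter(.data$registration_date <= .data$date) |>
      dplyr::distinct(.data$.row, .data$med_class)
    out[cbind(joined$.row, match(joined$med_class, classes))] <- TRUE
  }
  tibble::as_tibble(out)
}

#' Build measurement contexts for the CVD cohort
#'
#' Takes reliability-retained lipid panels and attaches, per measurement:
#' age and sex, CVD status within the measurement window, comorbidity flags
#' (diabetes by code or glucose-lowering prescription; hypertension by blood
#' pressure or prescription; CKD by code or eGFR), smoking status (most
#' recent observation on/before the date), medication-class flags and the
#' current statin with its atorvastatin-20 equivalents. Measurements of
#' patients under 18 or without established CVD are excluded and counted,
#' reproducing the selection flowchart.
#'
#' @param panels Retained panels ([apply_reliability_filter()]).
#' @param patients,diagnoses,prescriptions Validated tables.
#' @param bp,smoking Optional validated tables (may be `NULL`).
#' @param labs Labs table (for eGFR lookup).
#' @param config [cohort_config()].
#' @param equivalence Statin equivalence table.
#' @return Tibble of measurement contexts with an `exclusions` attribute
#'   (named counts: `under_18`, `non_cvd`).
#' @export
build_contexts <- function(panels, patients, diagnoses, prescriptions,
                           bp = NULL, smoking = NULL, labs = NULL,
                           config = cohort_config(),
                           equivalence = statin_equivalence_table()) {
  if (nrow(panels) == 0) {
    out <- empty_contexts()
    attr(out, "exclusions") <- c(under_18 = 0L, non_cvd = 0L)
    return(out)
  }
  ctx <- panels |>
    dplyr::left_join(dplyr::select(patients, "patient_id", "sex",
                                   "birth_date"),
                     by = "patient_id") |>
    dplyr::mutate(age_years =
                    as.numeric(.data$date - .data$birth_date) / 365.25)

  n0 <- nrow(ctx)
  ctx <- dplyr::filter(ctx, .data$age_years >= 18)
  n_under18 <- n0 - nrow(ctx)

  # CVD within window, vectorized: earliest qualifying event per patient
  cvd_ev <- diagnoses |>
    dplyr::filter(.data$category %in% cvd_categories()) |>
    dplyr::group_by(.data$patient_id, .data$category) |>
    dplyr::summarise(first_event = min(.data$date), .groups = "drop")
  cvd_flags <- ctx |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::left_join(cvd_ev, by = "patient_id",
                     relationship = "many-to-many") |>
    dplyr::filter(!is.na(.data$first_event),
                  .data$first_event <= .data$date + config$cvd_window_days) |>
    dplyr::group_by(.data$.row) |>
    dplyr::summarise(cvd_categories =
                       paste(sort(unique(.data$category)), collapse = ";"),
                     .groups = "drop")
  ctx$cvd <- FALSE
  ctx$cvd_categories <- ""
  ctx$cvd[cvd_flags$.row] <- TRUE
  ctx$cvd_categories[cvd_flags$.row] <- cvd_flags$cvd_categories

  n1 <- nrow(ctx)
  ctx <- dplyr::filter(ctx, .data$cvd)
  n_non_cvd <- n1 - nrow(ctx)
  if (nrow(ctx) == 0) {
    out <- empty_contexts()
    attr(out, "exclusions") <- c(under_18 = n_under18, non_cvd = n_non_cvd)
    return(out)
  }

  frame <- dplyr::select(ctx, "patient_id", "date")

  # diabetes: code OR glucose-lowering prescription on/before date
  dm_ev <- first_event_by_patient(diagnoses, "DIABETES", "dm_date")
  ctx$diabetes <- flag_on_or_before(frame, dm_ev, "dm_date")
  meds <- med_flags_at_measurements(frame, prescriptions)
  ctx$diabetes <- ctx$diabetes | meds$med_glucose_lowering

  # CKD: code OR low eGFR within window
  ckd_ev <- first_event_by_patient(diagnoses, c("CKD", "DIALYSIS"),
                                   "ckd_date")
  ctx$ckd <- flag_on_or_before(frame, ckd_ev, "ckd_date")
  if (!is.null(labs)) {
    egfr <- dplyr::filter(labs, .data$analyte == "eGFR")
    if (nrow(egfr) > 0) {
      low <- frame |>
        dplyr::mutate(.row = dplyr::row_number()) |>
        dplyr::left_join(dplyr::select(egfr, "patient_id",
                                       egfr_date = "date", "value"),
                         by = "patient_id",
                         relationship = "many-to-many") |>
        dplyr::filter(abs(as.integer(.data$egfr_date - .data$date)) <=
                        config$egfr_window_days,
                      .data$value < config$egfr_ckd_threshold)
      ctx$ckd[unique(low$.row)] <- TRUE
    }
  }

  # hypertension: BP > 140/90 nearest within window OR bp-lowering rx
  ctx$hypertension <- meds$med_bp_lowering
  if (!is.null(bp) && nrow(bp) > 0) {
    high <- frame |>
      dplyr::mutate(.row = dplyr::row_number()) |>
      dplyr::left_join(dplyr::select(bp, "patient_id", bp_date = "date",
                                     "systolic", "diastolic"),
                       by = "patient_id",
                       relationship = "many-to-many") |>
      dplyr::filter(!is.na(.data$bp_date),
                    abs(as.integer(.data$bp_date - .data$date)) <=
                      config$bp_window_days) |>
      dplyr::group_by(.data$.row) |>
      dplyr::slice_min(abs(as.integer(.data$bp_date - .data$date)), n = 1,
                       with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::filter(.data$systolic > 140 | .data$diastolic > 90)
    ctx$hypertension[high$.row] <- TRUE
  }

  # smoking: most recent dated observation on/before the measurement
  ctx$smoking_current <- NA
  if (!is.null(smoking) && nrow(smoking) > 0) {
    sm <- frame |>
      dplyr::mutate(.row = dplyr::row_number()) |>
      dplyr::left_join(dplyr::select(smoking, "patient_id",
                                     sm_date = "date", "smoking_current"),
                       by = "patient_id",
                       relationship = "many-to-many") |>
      dplyr::filter(.data$sm_date <= .data$date) |>
      dplyr::group_by(.data$.row) |>
      dplyr::slice_max(.data$sm_date, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    ctx$smoking_current[sm$.row] <- sm$smoking_current
  }

  st <- statin_at_measurements(frame, prescriptions, equivalence)
  out <- dplyr::bind_cols(
    dplyr::select(ctx, "patient_id", "date", "ldl", "ldl_source", "tg",
                  "age_years", "sex", "cvd", "cvd_categories", "diabetes",
                  "hypertension", "ckd", "smoking_current"),
    meds, st
  ) |>
    dplyr::arrange(.data$patient_id, .data$date)
  attr(out, "exclusions") <- c(under_18 = n_under18, non_cvd = n_non_cvd)
  out
}

first_event_by_patient <- function(diagnoses, cats, date_col) {
  ev <- dplyr::filter(diagnoses, .data$category %in% cats)
  if (nrow(ev) == 0) {
    out <- tibble::tibble(patient_id = character(),
                          date = as.Date(character()))
  } else {
    out <- ev |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(date = min(.data$date), .groups = "drop")
  }
  names(out)[2] <- date_col
  out
}

flag_on_or_before <- function(frame, events, date_col) {
  d <- events[[date_col]][match(frame$patient_id, events$patient_id)]
  !is.na(d) & d <= frame$date
}

empty_contexts <- function() {
  tibble::tibble(
    patient_id = character(), date = as.Date(character()), ldl = double(),
    ldl_source = character(), tg = double(), age_years = double(),
    sex = character(), cvd = logical(), cvd_categories = character(),
    diabetes = logical(), hypertension = logical(), ckd = logical(),
    smoking_current = logical(), med_statin = logical(),
    med_other_lipid_lowering = logical(), med_bp_lowering = logical(),
    med_glucose_lowering = logical(), med_antithrombotic = logical(),
    statin_type = character(), statin_dose_mg = double(),
    statin_equivalents = double()
  )
}
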