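#' Default LDL-c state transition matrix
#'
#' Transition probabilities between the six LDL-c categories across one
#' related follow-up step, as estimated from routine secondary-prevention
#' care; shipped as an editable CSV
#' (`inst/extdata/transition_matrix_default.csv`). Printed probabilities are
#' rounded to two decimals, so rows are renormalized to sum to exactly 1.
#'
#' @param path Optional replacement CSV (column `from_state` plus one column
#'   per state).
#' @return Row-stochastic 6x6 matrix with state dimnames.
#' @export
default_transition_matrix <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "transition_matrix_default.csv",
                        package = "ldltraj", mustWork = TRUE)
  }
  df <- readr::read_csv(path, col_types = readr::cols(
    from_state = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  lv <- ldl_state_levels()
  stopifnot(identical(df$from_state, lv), identical(names(df)[-1], lv))
  m <- as.matrix(df[, -1])
  rownames(m) <- lv
  m / rowSums(m)
}

#' Synthetic-cohort generator configuration
#'
#' Defines the study conditions the generator emulates: a six-state Markov
#' chain for LDL-c category trajectories, a covariate-driven logistic model
#' for baseline off-target status, a visit-interval mixture spanning the
#' too-soon / short-term / long-term / too-late regimes, the fraction of
#' patients measured only once, date-dependent availability of direct LDL-c
#' (derived-only before the remeasure date), and prescription/diagnosis
#' emission that encodes each latent covariate.
#'
#' @param n_patients Number of patients.
#' @param seed Integer RNG seed; identical config + seed gives identical
#'   output.
#' @param transition_matrix Row-stochastic 6x6 matrix over
#'   [ldl_state_levels()].
#' @param initial_state_distribution Length-6 probability vector; entries
#'   2-6, renormalized, give the off-target category at baseline (the
#'   on-target probability itself comes from `baseline_logit`); the full
#'   vector is the initial distribution for [simulate_state_sequences()].
#' @param single_measurement_fraction Probability a patient has exactly one
#'   measurement.
#' @param extra_measurement_lambda Measurement counts of repeated patients
#'   are `2 + Poisson(lambda)`, capped at `max_measurements`.
#' @param max_measurements Cap on measurements per patient.
#' @param interval_mixture List with `weights` and integer-day `ranges` for
#'   the four inter-visit components `too_soon`, `short`, `long`, `too_late`.
#' @param baseline_logit Named coefficients (log odds ratios) of the baseline
#'   off-target model: `intercept`, `age_per_year` (age centered at 65),
#'   `women`, `diabetes`, `hypertension`, `ckd`, `statin`, `antithrombotic`,
#'   `smoking`, `repeated`.
#' @param deterioration_coefficients Named log odds ratios for unfavorable
#'   change. `women` (and any other patient-level entries: `diabetes`,
#'   `hypertension`, `smoking`, `antithrombotic`, `age_per_year`) tilt the
#'   chain's on-target transition probability in [generate_cohort()]
#'   (prevalence-centered, so marginal transitions stay at
#'   `transition_matrix`); [simulate_change_pairs()] additionally honors
#'   `intercept`, statin-change levels (lower case), `measurement_index` and
#'   `follow_up_long`.
#' @param covariate_prevalences Named prevalences for `women`, `diabetes`,
#'   `hypertension`, `ckd`, `smoking`, `statin`, `antithrombotic`.
#' @param age_mean,age_sd,age_range Age at first measurement: normal,
#'   truncated to `age_range`.
#' @param date_range First-measurement dates drawn uniformly in this range.
#' @param missing_direct_ldl_fraction Fraction of panels on/after the
#'   remeasure date that still lack a direct LDL-c (all earlier panels are
#'   derived, as the laboratory then only used the Friedewald formula).
#' @param extra_lipids_fraction Fraction of direct-LDL panels that also carry
#'   a (consistent) TC/HDL/TG triplet.
#' @param ldl_cap Upper bound of the top LDL-c bin (mmol/L).
#' @param statin_change_prob Per-follow-up probability that a statin user
#'   gets a new statin prescription before that measurement.
#' @param egfr_fraction Fraction of non-CKD patients with an (unremarkable)
#'   eGFR measurement.
#' @param cohort [cohort_config()] supplying the target, reliability and
#'   follow-up thresholds the generator must agree with.
#' @return List of class `ldl_generator_config`.
#' @export
generator_config <- function(
    n_patients = 10000L,
    seed = 1L,
    transition_matrix = default_transition_matrix(),
    initial_state_distribution = c(0.49, 0.18, 0.15, 0.09, 0.05, 0.04),
    single_measurement_fraction = 0.55,
    extra_measurement_lambda = 2.77,
    max_measurements = 40L,
    interval_mixture = list(
      weights = c(too_soon = 0.10, short = 0.50, long = 0.34,
                  too_late = 0.06),
      ranges = list(too_soon = c(7L, 60L), short = c(61L, 183L),
                    long = c(184L, 548L), too_late = c(549L, 1200L))),
    baseline_logit = c(intercept = 0, age_per_year = log(0.99),
                       women = log(1.48), diabetes = log(0.69),
                       hypertension = log(0.87), ckd = log(0.75),
                       statin = log(0.86), antithrombotic = log(0.98),
                       smoking = log(1.29), repeated = log(1.25)),
    deterioration_coefficients = c(intercept = stats::qlogis(0.55),
                                   women = log(1.44)),
    covariate_prevalences = c(women = 0.31, diabetes = 0.12,
                              hypertension = 0.33, ckd = 0.007,
                              smoking = 0.10, statin = 0.33,
                              antithrombotic = 0.42),
    age_mean = 63, age_sd = 12, age_range = c(25, 90),
    date_range = as.Date(c("2003-02-01", "2017-11-30")),
    missing_direct_ldl_fraction = 0.35,
    extra_lipids_fraction = 0.3,
    ldl_cap = 8.0,
    statin_change_prob = 0.25,
    egfr_fraction = 0.4,
    cohort = cohort_config()) {
  cfg <- as.list(environment())
  cfg$n_patients <- as.integer(n_patients)
  cfg$seed <- as.integer(seed)
  validate_generator_config(cfg)
  structure(cfg, class = "ldl_generator_config")
}

validate_generator_config <- function(cfg) {
  tm <- cfg$transition_matrix
  stopifnot(cfg$n_patients > 0, is.matrix(tm), all(dim(tm) == 6),
            all(tm >= 0))
  if (any(abs(rowSums(tm) - 1) > 1e-9)) {
    stop("transition_matrix rows must sum to 1 (within 1e-9)", call. = FALSE)
  }
  isd <- cfg$initial_state_distribution
  stopifnot(length(isd) == 6, all(isd >= 0), sum(isd) > 0)
  frac <- c(cfg$single_measurement_fraction,
            cfg$missing_direct_ldl_fraction, cfg$extra_lipids_fraction,
            cfg$egfr_fraction, cfg$statin_change_prob,
            cfg$covariate_prevalences)
  stopifnot(all(frac >= 0 & frac <= 1))
  w <- cfg$interval_mixture$weights
  stopifnot(length(w) == 4, abs(sum(w) - 1) < 1e-9,
            identical(names(w), c("too_soon", "short", "long", "too_late")))
  stopifnot(cfg$extra_measurement_lambda >= 0, cfg$max_measurements >= 2,
            cfg$ldl_cap > cfg$cohort$ldl_target + 2)
  invisible(cfg)
}

statin_catalog <- function() {
  list(
    atorvastatin = list(atc = "C10AA05", doses = c(10, 20, 40, 80)),
    simvastatin = list(atc = "C10AA01", doses = c(10, 20, 40, 80)),
    rosuvastatin = list(atc = "C10AA07", doses = c(5, 10, 20, 40)),
    pravastatin = list(atc = "C10AA03", doses = c(10, 20, 40, 80))
  )
}

# prevalence-centered patient-level tilt on the unfavorable-change logit
trajectory_tilt <- function(pat, cfg) {
  b <- cfg$deterioration_coefficients
  prev <- cfg$covariate_prevalences
  tilt <- rep(0, nrow(pat))
  add <- function(tilt, name, x, center) {
    if (!is.na(b[name])) tilt + b[[name]] * (x - center) else tilt
  }
  b <- b[setdiff(names(b), c("intercept", "measurement_index",
                             "follow_up_long"))]
  tilt <- add(tilt, "women", as.numeric(pat$sex == "female"), prev[["women"]])
  for (v in c("diabetes", "hypertension", "smoking", "antithrombotic")) {
    tilt <- add(tilt, v, as.numeric(pat[[v]]), prev[[v]])
  }
  tilt <- add(tilt, "age_per_year", pat$age, 65)
  tilt
}

# one Markov step for all active chains, with a per-patient tilt on the
# on-target (favorable) probability; vectorized by current state
markov_step <- function(state, tilt, tm) {
  p_fav <- stats::plogis(stats::qlogis(tm[state, 1]) - tilt)
  fav <- stats::runif(length(state)) < p_fav
  nxt <- integer(length(state))
  nxt[fav] <- 1L
  for (s in sort(unique(state[!fav]))) {
    idx <- which(!fav & state == s)
    off <- tm[s, 2:6]
    nxt[idx] <- 1L + sample.int(5, length(idx), replace = TRUE, prob = off)
  }
  nxt
}

runif_int <- function(n, range) {
  as.integer(floor(stats::runif(n, range[1], range[2] + 1)))
}

#' Generate a synthetic EHR cohort with known ground truth
#'
#' Deterministic given `config$seed`. Emits the six EHR tables
#' ([ehr_table_names()]) conforming to the schemas, plus a truth object
#' sufficient to recompute every expected estimate. Every patient gets a CVD
#' event predating the first measurement; each latent covariate is encoded so
#' the preprocessing recovers it exactly (diabetics always carry a diabetes
#' code, hypertensives a blood-pressure-lowering prescription, CKD patients a
#' CKD code with low eGFR, and non-carriers none of these signals). Lipid
#' panels dated before the remeasure date are Friedewald-derived (TC/HDL/TG
#' emitted so the derivation reproduces the latent LDL-c exactly); later
#' panels carry a direct LDL-c unless hit by
#' `missing_direct_ldl_fraction`. The latent state chain advances exactly on
#' the measurements the greedy follow-up linker retains, so the estimated
#' transition matrix is an unbiased estimate of `transition_matrix` (up to
#' the prevalence-centered covariate tilt).
#'
#' @param config [generator_config()].
#' @return List with `tables` (named list of tibbles) and `truth`
#'   (class `ldl_synthetic_truth`: `config`, per-patient latent assignments,
#'   per-measurement latent states, injected-pathology counts).
#' @export
generate_cohort <- function(config = generator_config()) {
  validate_generator_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  prev <- config$covariate_prevalences
  ccfg <- config$cohort

  # latent patient covariates
  pat <- tibble::tibble(
    patient_id = sprintf("P%06d", seq_len(n)),
    sex = ifelse(stats::runif(n) < prev[["women"]], "female", "male"),
    age = pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd),
                    config$age_range[1]), config$age_range[2]),
    diabetes = stats::runif(n) < prev[["diabetes"]],
    hypertension = stats::runif(n) < prev[["hypertension"]],
    ckd = stats::runif(n) < prev[["ckd"]],
    smoking = stats::runif(n) < prev[["smoking"]],
    statin = stats::runif(n) < prev[["statin"]],
    antithrombotic = stats::runif(n) < prev[["antithrombotic"]],
    repeated = stats::runif(n) >= config$single_measurement_fraction
  )
  day_span <- as.integer(config$date_range[2] - config$date_range[1])
  pat$first_date <- config$date_range[1] + runif_int(n, c(0L, day_span))
  pat$birth_date <- pat$first_date - as.integer(round(pat$age * 365.25))

  # baseline off-target model
  b <- config$baseline_logit
  lp <- b[["intercept"]] + b[["age_per_year"]] * (pat$age - 65) +
    b[["women"]] * (pat$sex == "female") + b[["diabetes"]] * pat$diabetes +
    b[["hypertension"]] * pat$hypertension + b[["ckd"]] * pat$ckd +
    b[["statin"]] * pat$statin + b[["antithrombotic"]] * pat$antithrombotic +
    b[["smoking"]] * pat$smoking + b[["repeated"]] * pat$repeated
  pat$p_offtarget <- stats::plogis(lp)
  off <- stats::runif(n) < pat$p_offtarget
  init_off <- config$initial_state_distribution[2:6]
  baseline_state <- rep(1L, n)
  baseline_state[off] <- 1L + sample.int(5, sum(off), replace = TRUE,
                                         prob = init_off)
  pat$baseline_state <- baseline_state
  pat$n_measurements <- ifelse(
    pat$repeated,
    pmin(2L + stats::rpois(n, config$extra_measurement_lambda),
         config$max_measurements), 1L)

  # sequential visit simulation: the chain advances only on measurements the
  # greedy linker will retain, so generator and pipeline agree exactly
  tilt <- trajectory_tilt(pat, config)
  mix <- config$interval_mixture
  max_l <- max(pat$n_measurements)
  cur_time <- anchor_time <- rep(0L, n)
  anchor_state <- pat$baseline_state
  recs <- vector("list", max_l)
  recs[[1]] <- tibble::tibble(row = seq_len(n), index = 1L, time = 0L,
                              state = pat$baseline_state, related = NA)
  if (max_l >= 2) {
    for (s in 2:max_l) {
      act <- which(pat$n_measurements >= s)
      comp <- sample.int(4, length(act), replace = TRUE, prob = mix$weights)
      gap <- integer(length(act))
      for (k in 1:4) {
        sel <- comp == k
        if (any(sel)) gap[sel] <- runif_int(sum(sel), mix$ranges[[k]])
      }
      new_time <- cur_time[act] + gap
      delta <- new_time - anchor_time[act]
      related <- delta >= ccfg$short_min_days & delta <= ccfg$long_max_days
      state_s <- anchor_state[act]
      if (any(related)) {
        rel_idx <- act[related]
        state_s[related] <- markov_step(anchor_state[rel_idx],
                                        tilt[rel_idx],
                                        config$transition_matrix)
        anchor_time[rel_idx] <- new_time[related]
        anchor_state[rel_idx] <- state_s[related]
      }
      cur_time[act] <- new_time
      recs[[s]] <- tibble::tibble(row = act, index = s, time = new_time,
                                  state = state_s, related = related)
    }
  }
  meas <- dplyr::bind_rows(recs) |>
    dplyr::arrange(.data$row, .data$index)
  meas$patient_id <- pat$patient_id[meas$row]
  meas$date <- pat$first_date[meas$row] + meas$time

  # LDL-c uniform within the state's bin (never below the low-LDL cutoff,
  # so clean cohorts pass the reliability filter untouched)
  t0 <- ccfg$ldl_target
  lo <- c(ccfg$low_ldl_cutoff, t0, t0 + 0.5, t0 + 1.0, t0 + 1.5, t0 + 2.0)
  hi <- c(t0, t0 + 0.5, t0 + 1.0, t0 + 1.5, t0 + 2.0, config$ldl_cap)
  # 6 decimals keep CSV serialization byte-stable across write/read cycles
  meas$ldl <- round(stats::runif(nrow(meas), lo[meas$state], hi[meas$state]),
                    6)

  tables <- emit_tables(pat, meas, config)
  truth <- structure(
    list(config = config,
         patients = dplyr::select(pat, -dplyr::any_of("row")),
         measurements = dplyr::select(meas, "patient_id", "index", "date",
                                      "state", "related", "ldl"),
         injected = c(low_ldl_pre2017 = 0L, high_tg = 0L, under_18 = 0L,
                      non_cvd = 0L)),
    class = "ldl_synthetic_truth")
  list(tables = tables, truth = truth)
}

# materialize the EHR tables from latent patients + measurements
emit_tables <- function(pat, meas, config) {
  ccfg <- config$cohort
  n <- nrow(pat)
  m <- nrow(meas)

  patients <- tibble::tibble(patient_id = pat$patient_id, sex = pat$sex,
                             birth_date = pat$birth_date)

  # lipid labs: derived before the remeasure date, else direct unless hit by
  # the missing-direct fraction
  derived <- meas$date < ccfg$remeasure_date |
    stats::runif(m) < config$missing_direct_ldl_fraction
  hdl <- round(stats::runif(m, 0.8, 2.5), 2)
  tg <- round(stats::runif(m, 0.5, 4.0), 2)
  # rounding TC to 9 decimals keeps the Friedewald identity within 5e-10
  # while making the serialized value parse-stable
  tc <- round(meas$ldl + hdl + tg / 2.2, 9)
  extra <- !derived & stats::runif(m) < config$extra_lipids_fraction
  tri <- derived | extra
  labs <- dplyr::bind_rows(
    tibble::tibble(patient_id = meas$patient_id[tri], date = meas$date[tri],
                   analyte = "TC", value = tc[tri]),
    tibble::tibble(patient_id = meas$patient_id[tri], date = meas$date[tri],
                   analyte = "HDL", value = hdl[tri]),
    tibble::tibble(patient_id = meas$patient_id[tri], date = meas$date[tri],
                   analyte = "TG", value = tg[tri]),
    tibble::tibble(patient_id = meas$patient_id[!derived],
                   date = meas$date[!derived],
                   analyte = "LDL_direct", value = meas$ldl[!derived])
  )

  # eGFR: low for CKD patients (always), unremarkable for a fraction of the
  # rest — so eGFR-based CKD detection matches the latent flag exactly
  egfr_pat <- pat$ckd | stats::runif(n) < config$egfr_fraction
  egfr_val <- ifelse(pat$ckd, stats::runif(n, 20, 55),
                     stats::runif(n, 65, 110))
  labs <- dplyr::bind_rows(labs, tibble::tibble(
    patient_id = pat$patient_id[egfr_pat], date = pat$first_date[egfr_pat],
    analyte = "eGFR", value = round(egfr_val[egfr_pat], 1)))

  # diagnoses: one CVD event per patient predating measurements; diabetes
  # and CKD codes for carriers
  cvd_cat <- sample(cvd_categories(), n, replace = TRUE,
                    prob = c(0.62, 0.20, 0.13, 0.05))
  cvd_code <- c(CHD = "CHD01", STROKE = "STR01", PAD = "PAD01",
                AAA = "AAA01")[cvd_cat]
  diagnoses <- tibble::tibble(
    patient_id = pat$patient_id,
    date = pat$first_date - runif_int(n, c(30L, 3650L)),
    code = unname(cvd_code), category = cvd_cat)
  if (any(pat$diabetes)) {
    k <- sum(pat$diabetes)
    diagnoses <- dplyr::bind_rows(diagnoses, tibble::tibble(
      patient_id = pat$patient_id[pat$diabetes],
      date = pat$first_date[pat$diabetes] - runif_int(k, c(30L, 3650L)),
      code = "DM01", category = "DIABETES"))
  }
  if (any(pat$ckd)) {
    k <- sum(pat$ckd)
    diagnoses <- dplyr::bind_rows(diagnoses, tibble::tibble(
      patient_id = pat$patient_id[pat$ckd],
      date = pat$first_date[pat$ckd] - runif_int(k, c(30L, 3650L)),
      code = "CKD01", category = "CKD"))
  }

  # prescriptions encoding the medication covariates
  cat <- statin_catalog()
  rx <- list()
  if (any(pat$statin)) {
    k <- sum(pat$statin)
    type0 <- sample(names(cat), k, replace = TRUE)
    dose0 <- vapply(type0, function(ty) sample(cat[[ty]]$doses, 1), 0)
    rx$statin <- tibble::tibble(
      patient_id = pat$patient_id[pat$statin],
      registration_date = pat$first_date[pat$statin] -
        runif_int(k, c(7L, 1500L)),
      atc_code = unname(vapply(type0, function(ty) cat[[ty]]$atc, "")),
      drug_name = type0, daily_dose_mg = unname(dose0))
  }
  if (any(pat$hypertension)) {
    k <- sum(pat$hypertension)
    rx$bp <- tibble::tibble(
      patient_id = pat$patient_id[pat$hypertension],
      registration_date = pat$first_date[pat$hypertension] -
        runif_int(k, c(7L, 1500L)),
      atc_code = "C07AB02", drug_name = "metoprolol", daily_dose_mg = 100)
  }
  if (any(pat$antithrombotic)) {
    k <- sum(pat$antithrombotic)
    rx$at <- tibble::tibble(
      patient_id = pat$patient_id[pat$antithrombotic],
      registration_date = pat$first_date[pat$antithrombotic] -
        runif_int(k, c(7L, 1500L)),
      atc_code = "B01AC06", drug_name = "acetylsalicylic acid",
      daily_dose_mg = 80)
  }
  dm_rx <- pat$diabetes & stats::runif(n) < 0.6
  if (any(dm_rx)) {
    k <- sum(dm_rx)
    rx$glc <- tibble::tibble(
      patient_id = pat$patient_id[dm_rx],
      registration_date = pat$first_date[dm_rx] - runif_int(k, c(7L, 1500L)),
      atc_code = "A10BA02", drug_name = "metformin", daily_dose_mg = 1000)
  }
  # statin changes shortly before follow-up measurements
  fup <- meas[meas$index > 1 &
                meas$patient_id %in% pat$patient_id[pat$statin], ,
              drop = FALSE]
  if (nrow(fup) > 0) {
    chg <- stats::runif(nrow(fup)) < config$statin_change_prob
    fup <- fup[chg, , drop = FALSE]
    if (nrow(fup) > 0) {
      ty <- sample(names(cat), nrow(fup), replace = TRUE)
      rx$changes <- tibble::tibble(
        patient_id = fup$patient_id,
        registration_date = fup$date - runif_int(nrow(fup), c(0L, 6L)),
        atc_code = unname(vapply(ty, function(t) cat[[t]]$atc, "")),
        drug_name = ty,
        daily_dose_mg = unname(vapply(ty,
                                      function(t) sample(cat[[t]]$doses, 1),
                                      0)))
    }
  }
  prescriptions <- dplyr::bind_rows(rx)

  # blood pressure: below 140/90 for non-hypertensives (their absence of a
  # bp-lowering prescription must not be overridden), unrestricted otherwise
  sys <- ifelse(pat$hypertension, stats::runif(n, 115, 180),
                stats::runif(n, 100, 138))
  dia <- ifelse(pat$hypertension, sys - stats::runif(n, 25, 70),
                stats::runif(n, 60, 88))
  bp <- tibble::tibble(patient_id = pat$patient_id, date = pat$first_date,
                       systolic = round(sys), diastolic = round(pmax(dia, 40)))

  smoking <- tibble::tibble(patient_id = pat$patient_id,
                            date = pat$first_date,
                            smoking_current = pat$smoking)

  list(patients = patients, labs = labs, diagnoses = diagnoses,
       prescriptions = prescriptions, bp = bp, smoking = smoking)
}

#' Inject known pathological records
#'
#' Adds, as fresh tagged patients, the records each exclusion step must
#' catch: Friedewald panels with LDL-c below the low cutoff dated before the
#' remeasure date, Friedewald panels with triglycerides above the high
#' cutoff, under-18 patients, and patients without any CVD event. Counts are
#' recorded in the truth object so downstream exclusion totals are exactly
#' predictable.
#'
#' @param cohort Output of [generate_cohort()].
#' @param n_low_ldl,n_high_tg,n_under18,n_non_cvd Numbers of injected
#'   records of each kind.
#' @return The perturbed `list(tables, truth)`.
#' @export
inject_pathologies <- function(cohort, n_low_ldl = 0, n_high_tg = 0,
                               n_under18 = 0, n_non_cvd = 0) {
  tables <- cohort$tables
  truth <- cohort$truth
  ccfg <- truth$config$cohort
  add_patient <- function(tag, k, age, date_lo, date_hi, cvd) {
    ids <- sprintf("INJ%s%05d", tag, seq_len(k))
    dates <- date_lo + runif_int(k, c(0L, as.integer(date_hi - date_lo)))
    list(ids = ids, dates = dates,
         patients = tibble::tibble(
           patient_id = ids,
           sex = sample(c("female", "male"), k, replace = TRUE),
           birth_date = dates - as.integer(round(age * 365.25))),
         diagnoses = if (cvd) tibble::tibble(
           patient_id = ids, date = dates - 100L, code = "CHD01",
           category = "CHD") else NULL)
  }
  derived_panel <- function(ids, dates, ldl, tg) {
    ldl <- round(ldl, 6)
    hdl <- round(stats::runif(length(ids), 0.8, 2.5), 2)
    tc <- round(ldl + hdl + tg / 2.2, 9)
    dplyr::bind_rows(
      tibble::tibble(patient_id = ids, date = dates, analyte = "TC",
                     value = tc),
      tibble::tibble(patient_id = ids, date = dates, analyte = "HDL",
                     value = hdl),
      tibble::tibble(patient_id = ids, date = dates, analyte = "TG",
                     value = tg))
  }
  if (n_low_ldl > 0) {
    p <- add_patient("L", n_low_ldl, stats::runif(n_low_ldl, 40, 80),
                     as.Date("2005-01-01"), ccfg$remeasure_date - 30L, TRUE)
    tables$patients <- dplyr::bind_rows(tables$patients, p$patients)
    tables$diagnoses <- dplyr::bind_rows(tables$diagnoses, p$diagnoses)
    tables$labs <- dplyr::bind_rows(
      tables$labs,
      derived_panel(p$ids, p$dates,
                    stats::runif(n_low_ldl, 0.1, ccfg$low_ldl_cutoff - 0.05),
                    round(stats::runif(n_low_ldl, 0.5, 4.0), 2)))
  }
  if (n_high_tg > 0) {
    p <- add_patient("T", n_high_tg, stats::runif(n_high_tg, 40, 80),
                     as.Date("2005-01-01"), as.Date("2017-10-01"), TRUE)
    tables$patients <- dplyr::bind_rows(tables$patients, p$patients)
    tables$diagnoses <- dplyr::bind_rows(tables$diagnoses, p$diagnoses)
    tables$labs <- dplyr::bind_rows(
      tables$labs,
      derived_panel(p$ids, p$dates, stats::runif(n_high_tg, 1.0, 4.0),
                    round(stats::runif(n_high_tg, ccfg$high_tg_cutoff + 0.5,
                                       ccfg$high_tg_cutoff + 4), 2)))
  }
  if (n_under18 > 0) {
    p <- add_patient("U", n_under18, stats::runif(n_under18, 8, 17),
                     as.Date("2005-01-01"), as.Date("2017-10-01"), TRUE)
    tables$patients <- dplyr::bind_rows(tables$patients, p$patients)
    tables$diagnoses <- dplyr::bind_rows(tables$diagnoses, p$diagnoses)
    tables$labs <- dplyr::bind_rows(
      tables$labs,
      derived_panel(p$ids, p$dates, stats::runif(n_under18, 1.0, 4.0),
                    round(stats::runif(n_under18, 0.5, 4.0), 2)))
  }
  if (n_non_cvd > 0) {
    p <- add_patient("N", n_non_cvd, stats::runif(n_non_cvd, 40, 80),
                     as.Date("2005-01-01"), as.Date("2017-10-01"), FALSE)
    tables$patients <- dplyr::bind_rows(tables$patients, p$patients)
    tables$labs <- dplyr::bind_rows(
      tables$labs,
      derived_panel(p$ids, p$dates, stats::runif(n_non_cvd, 1.0, 4.0),
                    round(stats::runif(n_non_cvd, 0.5, 4.0), 2)))
  }
  truth$injected <- truth$injected +
    c(low_ldl_pre2017 = n_low_ldl, high_tg = n_high_tg,
      under_18 = n_under18, non_cvd = n_non_cvd)
  list(tables = tables, truth = truth)
}

#' Expected estimates from the generator's ground truth
#'
#' The oracle side of every recovery test: the true transition matrix,
#' true odds ratios, expected baseline off-target prevalence (averaged over
#' the realized covariates), expected single-measurement fraction,
#' stationary state distribution, expected pooled deterioration rate given
#' the realized related pairs, and expected exclusion counts from injected
#' pathologies.
#'
#' @param truth `ldl_synthetic_truth` object.
#' @return Named list of expected values.
#' @export
expected_estimates <- function(truth) {
  cfg <- truth$config
  tm <- cfg$transition_matrix
  eig <- eigen(t(tm))
  stat_idx <- which.min(abs(eig$values - 1))
  stationary <- Re(eig$vectors[, stat_idx])
  stationary <- stationary / sum(stationary)
  # expected pooled deterioration rate: condition on realized retained prev
  # states; the chain advances only on related measurements
  prev_states <- truth$measurements |>
    dplyr::filter(.data$related | is.na(.data$related)) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::filter(dplyr::n() >= 2,
                  dplyr::row_number() < dplyr::n()) |>
    dplyr::ungroup()
  exp_det <- if (nrow(prev_states) > 0) {
    1 - mean(tm[prev_states$state, 1])
  } else NA_real_
  bl <- cfg$baseline_logit
  list(
    transition_matrix = tm,
    stationary_distribution = stats::setNames(stationary,
                                              ldl_state_levels()),
    baseline_or = exp(bl[setdiff(names(bl), "intercept")]),
    deterioration_or = exp(cfg$deterioration_coefficients[
      setdiff(names(cfg$deterioration_coefficients), "intercept")]),
    offtarget_prevalence_first = mean(truth$patients$p_offtarget),
    single_fraction = cfg$single_measurement_fraction,
    expected_deterioration_rate = exp_det,
    exclusions = truth$injected
  )
}

#' Simulate bare state sequences from the generator's chain
#'
#' Covariate-free sequence simulator over the configured Markov chain:
#' initial states from `initial_state_distribution`, lengths
#' `2 + Poisson(extra_measurement_lambda)` capped at `max_measurements`, one
#' chain step per element. Used for transition-matrix recovery at scale
#' without materializing EHR tables.
#'
#' @param n_sequences Number of sequences.
#' @param config [generator_config()].
#' @param seed RNG seed (default: `config$seed`).
#' @return Long-format sequence tibble (`patient_id`, `index`, `state`)
#'   compatible with [transition_matrix()] and [truncate_sequences()].
#' @export
simulate_state_sequences <- function(n_sequences,
                                     config = generator_config(),
                                     seed = config$seed) {
  set.seed(seed)
  tm <- config$transition_matrix
  init <- config$initial_state_distribution /
    sum(config$initial_state_distribution)
  lens <- pmin(2L + stats::rpois(n_sequences,
                                 config$extra_measurement_lambda),
               config$max_measurements)
  cur <- sample.int(6, n_sequences, replace = TRUE, prob = init)
  recs <- vector("list", max(lens))
  recs[[1]] <- tibble::tibble(row = seq_len(n_sequences), index = 1L,
                              state = cur)
  for (s in 2:max(lens)) {
    act <- which(lens >= s)
    cur[act] <- markov_step(cur[act], rep(0, length(act)), tm)
    recs[[s]] <- tibble::tibble(row = act, index = s, state = cur[act])
  }
  out <- dplyr::bind_rows(recs) |>
    dplyr::arrange(.data$row, .data$index) |>
    dplyr::transmute(patient_id = sprintf("S%07d", .data$row),
                     index = .data$index,
                     state = factor(ldl_state_levels()[.data$state],
                                    levels = ldl_state_levels(),
                                    ordered = TRUE))
  out
}

#' Simulate measurement pairs from the deterioration model
#'
#' Pair-level simulator whose data-generating model is exactly the fitted
#' deterioration logistic: covariates drawn at the configured prevalences,
#' unfavorable change Bernoulli with logit
#' `intercept + x' deterioration_coefficients`; a favorable pair moves to on
#' target, an unfavorable one to an off-target category drawn from the
#' transition matrix row of the previous state restricted to off-target
#' columns.
#'
#' @param n_pairs Number of measurement pairs.
#' @param config [generator_config()].
#' @param seed RNG seed (default `config$seed`).
#' @return Tibble shaped like [change_pairs()] output (model columns).
#' @export
simulate_change_pairs <- function(n_pairs, config = generator_config(),
                                  seed = config$seed) {
  set.seed(seed)
  prev_p <- config$covariate_prevalences
  b <- config$deterioration_coefficients
  coef_of <- function(name) if (!is.na(b[name])) b[[name]] else 0
  tm <- config$transition_matrix
  df <- tibble::tibble(
    patient_id = sprintf("PAIR%07d", seq_len(n_pairs)),
    age_years = pmin(pmax(stats::rnorm(n_pairs, config$age_mean,
                                       config$age_sd),
                          config$age_range[1]), config$age_range[2]),
    sex = ifelse(stats::runif(n_pairs) < prev_p[["women"]],
                 "female", "male"),
    diabetes = stats::runif(n_pairs) < prev_p[["diabetes"]],
    hypertension = stats::runif(n_pairs) < prev_p[["hypertension"]],
    ckd = stats::runif(n_pairs) < prev_p[["ckd"]],
    smoking_current = stats::runif(n_pairs) < prev_p[["smoking"]],
    med_antithrombotic = stats::runif(n_pairs) < prev_p[["antithrombotic"]],
    statin_change = factor(sample(statin_change_levels(), n_pairs,
                                  replace = TRUE,
                                  prob = c(0.40, 0.06, 0.12, 0.08, 0.16,
                                           0.18)),
                           levels = statin_change_levels()),
    pair_index = sample.int(5, n_pairs, replace = TRUE),
    follow_up_type = factor(ifelse(stats::runif(n_pairs) < 0.4, "LONG",
                                   "SHORT"), levels = c("SHORT", "LONG"))
  )
  sc_coef <- stats::setNames(
    vapply(tolower(statin_change_levels()), coef_of, 0),
    statin_change_levels())
  lp <- coef_of("intercept") +
    coef_of("age_per_year") * (df$age_years - 65) +
    coef_of("women") * (df$sex == "female") +
    coef_of("diabetes") * df$diabetes +
    coef_of("hypertension") * df$hypertension +
    coef_of("smoking") * df$smoking_current +
    coef_of("antithrombotic") * df$med_antithrombotic +
    sc_coef[as.character(df$statin_change)] +
    coef_of("measurement_index") * df$pair_index +
    coef_of("follow_up_long") * (df$follow_up_type == "LONG")
  unfav <- stats::runif(n_pairs) < stats::plogis(lp)
  prev_state <- sample.int(6, n_pairs, replace = TRUE,
                           prob = config$initial_state_distribution /
                             sum(config$initial_state_distribution))
  nxt <- rep(1L, n_pairs)
  if (any(unfav)) {
    for (s in 1:6) {
      idx <- which(unfav & prev_state == s)
      if (length(idx) > 0) {
        nxt[idx] <- 1L + sample.int(5, length(idx), replace = TRUE,
                                    prob = tm[s, 2:6])
      }
    }
  }
  lv <- ldl_state_levels()
  df$prev_state <- factor(lv[prev_state], levels = lv, ordered = TRUE)
  df$next_state <- factor(lv[nxt], levels = lv, ordered = TRUE)
  df$change <- classify_change(df$prev_state, df$next_state)
  df
}
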