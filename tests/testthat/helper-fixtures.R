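# shared fixture builders; everything is generated in code

# long-format sequence tibble from a list of state-label vectors
mk_sequences <- function(states) {
  purrr::imap_dfr(states, function(s, i) {
    tibble::tibble(
      patient_id = sprintf("SEQ%03d", i),
      index = seq_along(s),
      state = factor(s, levels = ldl_state_levels(), ordered = TRUE)
    )
  })
}

# minimal measurement-context rows for trajectory/attainment tests
mk_contexts <- function(patient_id, dates, ldl,
                        sex = "male", diabetes = FALSE,
                        hypertension = FALSE, ckd = FALSE,
                        smoking = FALSE, statin = FALSE,
                        antithrombotic = FALSE, age = 60) {
  n <- length(dates)
  tibble::tibble(
    patient_id = rep_len(patient_id, n),
    date = as.Date(dates),
    ldl = rep_len(ldl, n),
    ldl_source = "measured",
    tg = NA_real_,
    age_years = rep_len(age, n),
    sex = rep_len(sex, n),
    cvd = TRUE,
    cvd_categories = "CHD",
    diabetes = rep_len(diabetes, n),
    hypertension = rep_len(hypertension, n),
    ckd = rep_len(ckd, n),
    smoking_current = rep_len(smoking, n),
    med_statin = rep_len(statin, n),
    med_other_lipid_lowering = FALSE,
    med_bp_lowering = FALSE,
    med_glucose_lowering = FALSE,
    med_antithrombotic = rep_len(antithrombotic, n),
    statin_type = NA_character_,
    statin_dose_mg = NA_real_,
    statin_equivalents = NA_real_
  )
}

# independent optimal-matching oracle: exhaustive enumeration of monotone
# alignments (every edit script corresponds to one; unmatched positions cost
# one indel each, matched pairs cost the substitution)
om_oracle <- function(a, b, sub, indel) {
  la <- length(a)
  lb <- length(b)
  best <- (la + lb) * indel
  for (k in seq_len(min(la, lb))) {
    ca <- utils::combn(la, k)
    cb <- utils::combn(lb, k)
    base <- indel * (la + lb - 2 * k)
    for (i in seq_len(ncol(ca))) {
      ai <- a[ca[, i]]
      for (j in seq_len(ncol(cb))) {
        cost <- base + sum(sub[cbind(ai, b[cb[, j]])])
        if (cost < best) best <- cost
      }
    }
  }
  best
}

# all integer sequences of lengths 1..max_len over alphabet 1..n_states
all_sequences <- function(n_states, max_len) {
  out <- list()
  for (len in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(seq_len(n_states)), len))
    out <- c(out, lapply(seq_len(nrow(grid)), function(r)
      as.integer(grid[r, ])))
  }
  out
}

# contexts assembled straight from generator truth (one row per patient at
# the first measurement, plus a dummy later row for repeated patients so the
# repetition stratum is right); used to isolate model fitting from the
# (deterministic) preprocessing when many replicates are needed
contexts_from_truth <- function(truth) {
  p <- truth$patients
  first <- mk_contexts("X", p$first_date, ldl_state_midpoint(
    ldl_state_levels()[p$baseline_state]))
  first$patient_id <- p$patient_id
  first$age_years <- p$age
  first$sex <- p$sex
  first$diabetes <- p$diabetes
  first$hypertension <- p$hypertension
  first$ckd <- p$ckd
  first$smoking_current <- p$smoking
  first$med_statin <- p$statin
  first$med_antithrombotic <- p$antithrombotic
  rep_rows <- first[p$repeated, , drop = FALSE]
  rep_rows$date <- rep_rows$date + 90
  dplyr::bind_rows(first, rep_rows)
}
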