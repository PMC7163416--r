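test_that("generation is deterministic given the seed", {
  g <- generator_config(n_patients = 200, seed = 4)
  a <- generate_cohort(g)
  b <- generate_cohort(g)
  expect_identical(a$tables, b$tables)
  expect_identical(a$truth$measurements, b$truth$measurements)
  c <- generate_cohort(generator_config(n_patients = 200, seed = 5))
  expect_false(identical(a$tables$labs, c$tables$labs))
})

test_that("generated tables conform to the schemas with zero rejects", {
  tb <- generate_cohort(generator_config(n_patients = 400, seed = 14))$tables
  for (nm in ehr_table_names()) {
    expect_silent(validate_table(tb[[nm]], nm))
  }
  # and read back through the full validating reader
  d <- withr::local_tempdir()
  write_tables(tb, d)
  expect_no_error(read_tables(d))
})

test_that("derived panels reproduce the latent LDL-c exactly", {
  cohort <- generate_cohort(generator_config(n_patients = 400, seed = 15))
  panels <- assemble_panels(cohort$tables$labs)
  truth <- cohort$truth$measurements
  joined <- dplyr::inner_join(panels, truth, by = c("patient_id", "date"),
                              suffix = c("", "_truth"))
  expect_equal(nrow(joined), nrow(truth))
  expect_lt(max(abs(joined$ldl - joined$ldl_truth)), 1e-9)
  fw <- joined[joined$ldl_source == "friedewald", ]
  expect_gt(nrow(fw), 0)
  expect_lt(max(abs(fw$tc - fw$hdl - fw$tg / 2.2 - fw$ldl)), 1e-9)
  # panels before the remeasure date are always derived
  pre <- joined$date < cohort$truth$config$cohort$remeasure_date
  expect_true(all(joined$ldl_source[pre] == "friedewald"))
})

test_that("the single-measurement fraction matches its configured value", {
  g <- generator_config(n_patients = 6000, seed = 16)
  truth <- generate_cohort(g)$truth
  frac <- mean(truth$patients$n_measurements == 1)
  se <- sqrt(0.55 * 0.45 / 6000)
  expect_lt(abs(frac - g$single_measurement_fraction), 3 * se)
})

test_that("an identity transition matrix freezes every trajectory", {
  id6 <- diag(6)
  g <- generator_config(n_patients = 300, seed = 18, transition_matrix = id6)
  truth <- generate_cohort(g)$truth
  per_pat <- tapply(truth$measurements$state, truth$measurements$patient_id,
                    function(s) length(unique(s)))
  expect_true(all(per_pat == 1))
  seqs <- simulate_state_sequences(200, generator_config(
    seed = 18, transition_matrix = id6))
  per_seq <- tapply(as.character(seqs$state), seqs$patient_id,
                    function(s) length(unique(s)))
  expect_true(all(per_seq == 1))
})

test_that("injected pathologies are excluded in exactly the injected numbers", {
  cohort <- generate_cohort(generator_config(n_patients = 300, seed = 19))
  cohort <- inject_pathologies(cohort, n_low_ldl = 50, n_high_tg = 100,
                               n_under18 = 20, n_non_cvd = 30)
  tb <- cohort$tables
  panels <- assemble_panels(tb$labs)
  filt <- apply_reliability_filter(panels)
  expect_equal(sum(filt$excluded$exclusion_reason == "low_ldl_pre2017"), 50)
  expect_equal(sum(filt$excluded$exclusion_reason == "high_tg"), 100)
  ctx <- build_contexts(filt$retained, tb$patients, tb$diagnoses,
                        tb$prescriptions, bp = tb$bp, smoking = tb$smoking,
                        labs = tb$labs)
  excl <- attr(ctx, "exclusions")
  expect_equal(unname(excl[["under_18"]]), 20)
  expect_equal(unname(excl[["non_cvd"]]), 30)
  # injected low-LDL panels dated after the remeasure date are retained
  g2 <- generate_cohort(generator_config(n_patients = 50, seed = 20))
  late_low <- tibble::tibble(
    patient_id = g2$tables$patients$patient_id[1],
    date = as.Date("2017-06-01"), analyte = "LDL_direct", value = 0.5)
  labs2 <- dplyr::bind_rows(g2$tables$labs, late_low)
  filt2 <- apply_reliability_filter(assemble_panels(labs2))
  expect_true(as.Date("2017-06-01") %in%
                filt2$retained$date[filt2$retained$ldl == 0.5])
})

test_that("expected estimates expose the generator truth", {
  g <- generator_config(n_patients = 150, seed = 22,
                        transition_matrix = diag(6))
  truth <- generate_cohort(g)$truth
  est <- expected_estimates(truth)
  expect_equal(unname(diag(est$transition_matrix)), rep(1, 6))
  expect_equal(unname(est$baseline_or[["women"]]), 1.48)
  expect_equal(unname(est$deterioration_or[["women"]]), 1.44)
  expect_equal(est$single_fraction, 0.55)
  expect_true(est$offtarget_prevalence_first > 0 &&
                est$offtarget_prevalence_first < 1)
  # identity chain: the next state is on target iff the previous one is, so
  # the expected deterioration rate is the off-target share at the previous
  # position of the retained pairs
  prevs <- truth$measurements |>
    dplyr::filter(related | is.na(related)) |>
    dplyr::group_by(patient_id) |>
    dplyr::filter(dplyr::n() >= 2, dplyr::row_number() < dplyr::n()) |>
    dplyr::ungroup()
  expect_equal(est$expected_deterioration_rate, mean(prevs$state != 1L))
})

test_that("truth-level contexts match pipeline contexts for model fitting", {
  cohort <- generate_cohort(generator_config(n_patients = 3000, seed = 25))
  tb <- cohort$tables
  ctx <- build_contexts(
    apply_reliability_filter(assemble_panels(tb$labs))$retained,
    tb$patients, tb$diagnoses, tb$prescriptions, bp = tb$bp,
    smoking = tb$smoking, labs = tb$labs)
  fit_pipeline <- offtarget_logistic(ctx)
  fit_truth <- offtarget_logistic(contexts_from_truth(cohort$truth))
  expect_equal(fit_truth$or, fit_pipeline$or, tolerance = 1e-6)
})
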