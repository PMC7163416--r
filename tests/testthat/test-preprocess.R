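mk_labs <- function(...) {
  rows <- list(...)
  purrr::map_dfr(rows, function(r) {
    tibble::tibble(patient_id = r[[1]], date = as.Date(r[[2]]),
                   analyte = r[[3]], value = as.numeric(r[[4]]))
  })
}

test_that("Friedewald derivation follows the mmol/L formula", {
  expect_equal(friedewald_ldl(5.0, 1.0, 2.2), 3.0)
  expect_equal(friedewald_ldl(3.7, 3.7, 0), 0.0)
  # negative results are possible (high TG); the caller filters them
  expect_equal(friedewald_ldl(4.0, 1.0, 8.8), -1.0)
  expect_true(is.na(friedewald_ldl(5.0, NA, 2.2)))
  expect_error(friedewald_ldl(5.0, -1.0, 2.2), "negative")
})

test_that("panel assembly requires a direct LDL-c or a full lipid triplet", {
  labs <- mk_labs(
    list("P1", "2010-01-01", "TC", 5.0), # TC+HDL only: no panel
    list("P1", "2010-01-01", "HDL", 1.0),
    list("P2", "2010-02-01", "TC", 5.0), # full triplet: friedewald
    list("P2", "2010-02-01", "HDL", 1.0),
    list("P2", "2010-02-01", "TG", 2.2),
    list("P3", "2010-03-01", "LDL_direct", 2.0), # direct preferred
    list("P3", "2010-03-01", "TC", 6.0),
    list("P3", "2010-03-01", "HDL", 1.0),
    list("P3", "2010-03-01", "TG", 2.2)
  )
  panels <- assemble_panels(labs)
  expect_equal(nrow(panels), 2)
  expect_equal(attr(panels, "n_incomplete"), 1L)
  p2 <- panels[panels$patient_id == "P2", ]
  expect_equal(p2$ldl_source, "friedewald")
  expect_equal(p2$ldl, 3.0)
  p3 <- panels[panels$patient_id == "P3", ]
  expect_equal(p3$ldl_source, "measured")
  expect_equal(p3$ldl, 2.0)
})

test_that("reliability filter applies the low-LDL date rule and TG rule", {
  panels <- tibble::tibble(
    patient_id = c("A", "B", "C", "D"),
    date = as.Date(c("2016-05-01", "2017-06-01", "2012-01-01", "2012-01-01")),
    tc = c(NA, NA, 6, 6), hdl = c(NA, NA, 1, 1),
    tg = c(NA, NA, 9.0, 4.0),
    ldl = c(0.5, 0.5, 0.9, 3.2),
    ldl_source = c("measured", "measured", "friedewald", "friedewald")
  )
  out <- apply_reliability_filter(panels)
  expect_equal(sort(out$excluded$patient_id), c("A", "C"))
  expect_equal(out$excluded$exclusion_reason[out$excluded$patient_id == "A"],
               "low_ldl_pre2017")
  expect_equal(out$excluded$exclusion_reason[out$excluded$patient_id == "C"],
               "high_tg")
  expect_equal(sort(out$retained$patient_id), c("B", "D"))
  # conservation: retained + excluded = input as a multiset
  expect_equal(
    dplyr::arrange(dplyr::bind_rows(out$retained,
                                    dplyr::select(out$excluded,
                                                  -"exclusion_reason")),
                   patient_id),
    dplyr::arrange(panels, patient_id))
})

test_that("high-TG exclusion only hits friedewald panels and is monotone in the cutoff", {
  set.seed(41)
  n <- 400
  panels <- tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    date = as.Date("2015-01-01") + sample.int(2000, n, replace = TRUE),
    tc = runif(n, 3, 9), hdl = runif(n, 0.8, 2.5),
    tg = runif(n, 0.5, 12),
    ldl = runif(n, 0.9, 5),
    ldl_source = sample(c("measured", "friedewald"), n, replace = TRUE)
  )
  retained_n <- vapply(c(6, 8, 10), function(cut) {
    nrow(apply_reliability_filter(panels,
                                  cohort_config(high_tg_cutoff = cut))$retained)
  }, 0L)
  expect_true(all(diff(retained_n) >= 0))
  out <- apply_reliability_filter(panels, cohort_config(high_tg_cutoff = 8))
  expect_true(all(out$excluded$ldl_source[out$excluded$exclusion_reason ==
                                            "high_tg"] == "friedewald"))
})

test_that("CVD status uses the one-week look-ahead window and is monotone in date", {
  dg <- tibble::tibble(patient_id = "P1", date = as.Date("2010-01-01"),
                       code = "CHD01", category = "CHD")
  expect_true(cvd_status_at("P1", as.Date("2010-06-01"), dg)$cvd)
  expect_equal(cvd_status_at("P1", as.Date("2010-06-01"), dg)$categories,
               "CHD")
  # event shortly after the measurement still qualifies (preop screening)
  expect_true(cvd_status_at("P1", as.Date("2009-12-29"), dg)$cvd)
  expect_false(cvd_status_at("P1", as.Date("2009-12-01"), dg)$cvd)
  expect_false(cvd_status_at("P2", as.Date("2010-06-01"), dg)$cvd)
  # monotone: once CVD, always CVD at later dates
  dates <- as.Date("2009-12-20") + 0:30
  flags <- vapply(dates, function(d) cvd_status_at("P1", d, dg)$cvd, TRUE)
  expect_true(all(diff(as.integer(flags)) >= 0))
})

test_that("ATC prefixes map to the expected medication classes", {
  expect_equal(
    classify_medication(c("C10AA05", "A10BA02", "B01AC06", "B02AB01",
                          "C10AB04", "C07AB02", "C09AA02", "J01CA04")),
    c("statin", "glucose_lowering", "antithrombotic", "antithrombotic",
      "other_lipid_lowering", "bp_lowering", "bp_lowering", NA))
})

test_that("hypertension combines blood pressure and prescriptions", {
  bp <- tibble::tibble(patient_id = c("P1", "P2"),
                       date = as.Date("2010-01-01"),
                       systolic = c(150, 135), diastolic = c(80, 85))
  rx <- tibble::tibble(patient_id = "P3",
                       registration_date = as.Date("2009-01-01"),
                       atc_code = "C07AB02", drug_name = "metoprolol",
                       daily_dose_mg = 100)
  none <- rx[0, ]
  d <- as.Date("2010-01-01")
  expect_true(hypertension_at("P1", d, bp, none))
  expect_false(hypertension_at("P2", d, bp, none))
  expect_true(hypertension_at("P3", d, NULL, rx))
  # prescription after the measurement date does not count
  expect_false(hypertension_at("P3", as.Date("2008-06-01"), NULL, rx))
})

test_that("CKD combines codes and the eGFR window", {
  labs <- mk_labs(list("P1", "2010-01-04", "eGFR", 45),
                  list("P2", "2009-12-26", "eGFR", 45))
  dg <- tibble::tibble(patient_id = "P3", date = as.Date("2005-01-01"),
                       code = "DIAL01", category = "DIALYSIS")
  d <- as.Date("2010-01-05")
  expect_true(ckd_at("P1", d, dg[0, ], labs))   # 1 day before, eGFR 45
  expect_false(ckd_at("P2", d, dg[0, ], labs))  # 10 days before: outside
  expect_true(ckd_at("P3", d, dg, labs))        # dialysis code
})

test_that("statin equivalents are linear and anchored at atorvastatin 20", {
  expect_equal(statin_equivalent_dose("atorvastatin", 20), 1.0)
  expect_equal(statin_equivalent_dose("atorvastatin", 40), 2.0)
  expect_equal(statin_equivalent_dose("simvastatin", 40), 1.0)
  expect_equal(statin_equivalent_dose("rosuvastatin", 5), 0.5)
  expect_warning(res <- statin_equivalent_dose("cerivastatin", 10),
                 "unmapped")
  expect_true(is.na(res))
})

test_that("context building reproduces the exclusion flowchart counts", {
  cohort <- generate_cohort(generator_config(n_patients = 250, seed = 9))
  cohort <- inject_pathologies(cohort, n_under18 = 12, n_non_cvd = 17)
  tb <- cohort$tables
  panels <- assemble_panels(tb$labs)
  filt <- apply_reliability_filter(panels)
  ctx <- build_contexts(filt$retained, tb$patients, tb$diagnoses,
                        tb$prescriptions, bp = tb$bp, smoking = tb$smoking,
                        labs = tb$labs)
  excl <- attr(ctx, "exclusions")
  expect_equal(unname(excl[["under_18"]]), 12)
  expect_equal(unname(excl[["non_cvd"]]), 17)
  expect_equal(nrow(filt$retained), nrow(ctx) + sum(excl))
  # latent covariates are recovered exactly at the first measurement
  firsts <- ctx |>
    dplyr::filter(!startsWith(patient_id, "INJ")) |>
    dplyr::arrange(patient_id, date) |>
    dplyr::distinct(patient_id, .keep_all = TRUE)
  truth <- cohort$truth$patients
  truth <- truth[match(firsts$patient_id, truth$patient_id), ]
  expect_equal(firsts$diabetes, truth$diabetes)
  expect_equal(firsts$hypertension, truth$hypertension)
  expect_equal(firsts$ckd, truth$ckd)
  expect_equal(firsts$smoking_current, truth$smoking)
  expect_equal(firsts$med_statin, truth$statin)
  expect_equal(firsts$med_antithrombotic, truth$antithrombotic)
})
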