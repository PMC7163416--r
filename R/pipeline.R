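#' Run the full LDL-c management pipeline
#'
#' Orchestrates preprocessing, target attainment, trajectory, clustering and
#' change analyses over EHR tables read from `input_dir` (or generated with
#' `simulate`), writes all report CSVs to `out_dir`, and records the
#' exclusion flowchart and conservation counts in `manifest.json`. Cohorts in
#' which no patient has two related measurements are legitimate: the
#' trajectory, clustering and change stages then emit empty outputs with an
#' explicit notice while the baseline stages complete.
#'
#' @param out_dir Output directory (created).
#' @param input_dir Directory with the input CSVs; ignored when `simulate`
#'   is given.
#' @param config [cohort_config()].
#' @param simulate Optional [generator_config()]; when supplied the cohort is
#'   generated (and written under `out_dir/simulated/`) instead of read.
#' @param stages Character subset of
#'   `c("target_attainment", "trajectories", "clustering", "change")`;
#'   preprocessing always runs.
#' @param distances_csv_max Write the condensed pairwise-distance CSV only
#'   when the number of sequences does not exceed this (the matrix grows
#'   quadratically).
#' @param code_map Diagnosis code map.
#' @param equivalence Statin equivalence table.
#' @return The manifest, invisibly; side effect: CSVs + `manifest.json` in
#'   `out_dir`.
#' @export
run_pipeline <- function(out_dir,
                         input_dir = NULL,
                         config = cohort_config(),
                         simulate = NULL,
                         stages = c("target_attainment", "trajectories",
                                    "clustering", "change"),
                         distances_csv_max = 1000,
                         code_map = cvd_code_map(),
                         equivalence = statin_equivalence_table()) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   config = unclass(config), counts = list(),
                   notices = character(0), outputs = character(0))

  if (!is.null(simulate)) {
    sim <- generate_cohort(simulate)
    sim_dir <- file.path(out_dir, "simulated")
    write_tables(sim$tables, sim_dir)
    tables <- read_tables(sim_dir, code_map = code_map)
    manifest$seed <- simulate$seed
    manifest$input_dir <- sim_dir
  } else {
    stopifnot(!is.null(input_dir))
    tables <- read_tables(input_dir, code_map = code_map)
    manifest$input_dir <- input_dir
  }
  files <- file.path(manifest$input_dir,
                     paste0(names(tables), ".csv"))
  manifest$input_digests <- as.list(tools::md5sum(files[file.exists(files)]))
  manifest$counts$input_rows <- as.list(attr(tables, "row_counts"))

  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(df, path, progress = FALSE)
    manifest$outputs <<- c(manifest$outputs, name)
  }
  notice <- function(msg) {
    manifest$notices <<- c(manifest$notices, msg)
    message("[ldltraj] ", msg)
  }

  # --- preprocess ---------------------------------------------------------
  panels <- assemble_panels(tables$labs)
  filt <- apply_reliability_filter(panels, config)
  contexts <- build_contexts(filt$retained, tables$patients,
                             tables$diagnoses, tables$prescriptions,
                             bp = tables$bp, smoking = tables$smoking,
                             labs = tables$labs, config = config,
                             equivalence = equivalence)
  excl <- attr(contexts, "exclusions")
  manifest$counts$flowchart <- list(
    panels_total = nrow(panels),
    incomplete_dates = attr(panels, "n_incomplete"),
    excluded_low_ldl = sum(filt$excluded$exclusion_reason ==
                             "low_ldl_pre2017"),
    excluded_high_tg = sum(filt$excluded$exclusion_reason == "high_tg"),
    retained_reliable = nrow(filt$retained),
    excluded_under_18 = unname(excl[["under_18"]]),
    excluded_non_cvd = unname(excl[["non_cvd"]]),
    cvd_measurements = nrow(contexts),
    cvd_patients = length(unique(contexts$patient_id))
  )
  stopifnot(nrow(panels) == nrow(filt$retained) + nrow(filt$excluded),
            nrow(filt$retained) == nrow(contexts) + excl[["under_18"]] +
              excl[["non_cvd"]])
  emit(dplyr::bind_rows(
    dplyr::mutate(filt$excluded, step = "reliability",
                  reason = .data$exclusion_reason)[, c("patient_id", "date",
                                                       "step", "reason")]),
    "exclusions.csv")

  if (nrow(contexts) == 0) {
    notice("no CVD measurements retained; downstream stages not computed")
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    return(invisible(manifest))
  }

  strata <- split_by_repetition(contexts)
  manifest$counts$patients_single <- unname(strata$counts[["single"]])
  manifest$counts$patients_repeated <- unname(strata$counts[["repeated"]])

  # --- target attainment --------------------------------------------------
  if ("target_attainment" %in% stages) {
    emit(attainment_prevalence(contexts, "overall", config, first_only = TRUE),
         "attainment_overall.csv")
    emit(attainment_prevalence(contexts, "per_year", config),
         "attainment_by_year.csv")
    emit(attainment_prevalence(contexts, "per_stratum", config,
                               first_only = TRUE),
         "attainment_by_stratum.csv")
    emit(baseline_table(contexts, config), "baseline_table.csv")
    emit(state_histogram(contexts, config), "state_histogram.csv")
    or_tab <- tryCatch(offtarget_logistic(contexts, config),
                       error = function(e) {
                         notice(paste("off-target model not computed:",
                                      conditionMessage(e)))
                         NULL
                       })
    if (!is.null(or_tab)) emit(or_tab, "offtarget_or.csv")
  }

  # --- trajectories -------------------------------------------------------
  sequences <- link_measurements(contexts, config)
  disc <- attr(sequences, "discards")
  manifest$counts$trajectories <- list(
    measurements_in = nrow(contexts),
    unrelated_discarded = unname(disc[["unrelated"]]),
    singleton_measurements_dropped = unname(disc[["singleton_measurements"]]),
    sequence_measurements = nrow(sequences),
    sequences = length(unique(sequences$patient_id))
  )
  need_traj <- any(c("trajectories", "clustering", "change") %in% stages)
  if (need_traj && nrow(sequences) == 0) {
    notice("no related repeated measurements; trajectory stages emit empty outputs")
    emit(tibble::tibble(patient_id = character(), index = integer(),
                        date = as.Date(character()), state = character(),
                        follow_up_type = character()), "sequences.csv")
    emit(tibble::tibble(index = integer(), state = character(),
                        n = integer(), proportion = double()),
         "state_distributions.csv")
  } else if (need_traj) {
    truncated <- truncate_sequences(sequences, config$truncation_percentile)
    manifest$counts$truncation_cutoff <- attr(truncated, "cutoff")
    manifest$counts$truncated_measurements <- nrow(truncated)
    tmat_input <- if (config$transitions_on_truncated) truncated else
      sequences
    if ("trajectories" %in% stages) {
      emit(sequences, "sequences.csv")
      tmat <- transition_matrix(tmat_input)
      manifest$counts$pooled_pairs <- unname(sum(tmat$row_totals))
      counts_df <- tibble::as_tibble(tmat$counts, rownames = "from_state")
      probs_df <- tibble::as_tibble(round(tmat$probs, 6),
                                    rownames = "from_state")
      emit(counts_df, "transition_counts.csv")
      emit(probs_df, "transition_probs.csv")
      emit(state_distributions(truncated), "state_distributions.csv")
    }

    # --- sequence clustering ---------------------------------------------
    if ("clustering" %in% stages) {
      n_seq <- length(unique(truncated$patient_id))
      if (n_seq <= config$n_clusters) {
        notice("too few sequences to cluster; clustering not computed")
      } else {
        costs <- if (config$substitution_method == "trate") {
          substitution_costs("trate", transition_matrix(tmat_input))
        } else {
          substitution_costs("constant",
                             constant_value = config$substitution_constant)
        }
        dmat <- pairwise_distances(truncated, costs, config$indel_cost)
        labels <- cluster_sequences(dmat, config$n_clusters)
        emit(tibble::tibble(patient_id = names(labels),
                            cluster = as.integer(labels)), "clusters.csv")
        emit(cluster_summaries(labels, truncated), "cluster_summaries.csv")
        emit(silhouette_by_k(dmat), "silhouette_by_k.csv")
        if (nrow(dmat) <= distances_csv_max) {
          pairs_idx <- which(upper.tri(dmat), arr.ind = TRUE)
          emit(tibble::tibble(id_a = rownames(dmat)[pairs_idx[, 1]],
                              id_b = colnames(dmat)[pairs_idx[, 2]],
                              distance = dmat[pairs_idx]), "distances.csv")
        } else {
          notice("distances.csv skipped (too many sequences)")
        }
        covars <- first_measurements(contexts) |>
          dplyr::transmute(patient_id = .data$patient_id,
                           age = .data$age_years,
                           women = .data$sex == "female",
                           diabetes = .data$diabetes,
                           hypertension = .data$hypertension,
                           smoking = .data$smoking_current,
                           statin = .data$med_statin,
                           antithrombotic = .data$med_antithrombotic)
        cl_or <- tryCatch(
          suppressWarnings(cluster_covariate_model(labels, covars)),
          error = function(e) {
            notice(paste("cluster covariate model not computed:",
                         conditionMessage(e)))
            NULL
          })
        if (!is.null(cl_or) && nrow(cl_or) > 0) emit(cl_or, "cluster_or.csv")
      }
    }

    # --- change analysis ---------------------------------------------------
    if ("change" %in% stages) {
      pairs <- change_pairs(sequences, contexts, equivalence)
      manifest$counts$change <- list(
        pairs_total = nrow(pairs),
        pairs_statin_not_evaluable = unname(attr(pairs, "n_not_evaluable"))
      )
      emit(pairs, "change_pairs.csv")
      det <- tryCatch(deterioration_logistic(pairs),
                      error = function(e) {
                        notice(paste("deterioration model not computed:",
                                     conditionMessage(e)))
                        NULL
                      })
      if (!is.null(det)) emit(det, "deterioration_or.csv")
    }
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Render a plain-text summary report
#'
#' Assembles the pipeline outputs in `out_dir` into one text document: the
#' selection flowchart (total, reliable, CVD, single/repeated), attainment,
#' baseline characteristics, the odds-ratio tables, the transition matrix and
#' the cluster summaries. Sections whose CSVs are absent are marked
#' "not computed".
#'
#' @param out_dir Directory holding the pipeline outputs.
#' @param file Output file (default `report.txt` inside `out_dir`).
#' @return The report path, invisibly.
#' @export
render_report <- function(out_dir, file = file.path(out_dir, "report.txt")) {
  manifest_path <- file.path(out_dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("missing manifest.json in ", out_dir, call. = FALSE)
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  section <- function(title, csv, render = NULL) {
    w("", paste0("== ", title, " =="))
    path <- file.path(out_dir, csv)
    if (!file.exists(path)) {
      w("not computed")
      return(invisible(NULL))
    }
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (nrow(df) == 0) {
      w("not computed (empty)")
    } else {
      utils::capture.output(print(as.data.frame(df))) |> writeLines(con = con)
    }
  }
  w("LDL-c management pipeline report")
  w("generated: ", manifest$created)
  fc <- manifest$counts$flowchart
  w("", "== Selection flowchart ==")
  w("lipid panels assembled:           ", fc$panels_total)
  w("  excluded, low LDL-c (pre-remeasure): ", fc$excluded_low_ldl)
  w("  excluded, high triglycerides:   ", fc$excluded_high_tg)
  w("reliable measurements:            ", fc$retained_reliable)
  w("  excluded, under 18:             ", fc$excluded_under_18)
  w("  excluded, no established CVD:   ", fc$excluded_non_cvd)
  w("CVD measurements:                 ", fc$cvd_measurements)
  w("CVD patients:                     ", fc$cvd_patients)
  w("  with repeated measurements:     ",
    manifest$counts$patients_repeated %||% 0)
  w("  with a single measurement:      ",
    manifest$counts$patients_single %||% 0)
  section("Target attainment (first measurement)", "attainment_overall.csv")
  section("Target attainment per year", "attainment_by_year.csv")
  section("Baseline characteristics", "baseline_table.csv")
  section("Off-target at first measurement: odds ratios", "offtarget_or.csv")
  section("Transition probabilities", "transition_probs.csv")
  section("State distributions per measurement", "state_distributions.csv")
  section("Sequence clusters", "cluster_summaries.csv")
  section("Cluster membership: odds ratios", "cluster_or.csv")
  section("Deterioration: odds ratios", "deterioration_or.csv")
  if (length(manifest$notices) > 0) {
    w("", "== Notices ==")
    for (msg in manifest$notices) w("- ", msg)
  }
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
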