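#' Classify a follow-up interval
#'
#' Short-term evaluation when the gap from the previous (retained)
#' measurement lies in `[short_min_days, short_max_days]` (defaults 61-183
#' days, i.e. 2-6 months), long-term when in `(short_max_days,
#' long_max_days]` (6-18 months); anything sooner or later is unrelated to
#' clinical evaluation of the previous measurement. The three classes
#' partition the positive integers; the shared 6-month boundary belongs to
#' the short-term window.
#'
#' @param delta_days Positive integer vector of inter-measurement gaps.
#' @param config [cohort_config()].
#' @return Factor with levels `SHORT`, `LONG`, `UNRELATED`.
#' @export
classify_follow_up <- function(delta_days, config = cohort_config()) {
  if (any(delta_days <= 0)) {
    stop("classify_follow_up(): non-positive interval (measurements must be ",
         "strictly ordered)", call. = FALSE)
  }
  out <- dplyr::case_when(
    delta_days >= config$short_min_days &
      delta_days <= config$short_max_days ~ "SHORT",
    delta_days > config$short_max_days &
      delta_days <= config$long_max_days ~ "LONG",
    TRUE ~ "UNRELATED"
  )
  factor(out, levels = c("SHORT", "LONG", "UNRELATED"))
}

#' Link repeated measurements into state sequences
#'
#' Greedy forward chaining per patient: the first measurement anchors the
#' sequence; each subsequent measurement is retained iff its interval from
#' the last retained measurement classifies as short- or long-term follow-up,
#' and discarded as unrelated otherwise. Patients left with fewer than two
#' retained measurements contribute no sequence (their retained measurement
#' is counted as a dropped singleton).
#'
#' @param contexts Measurement contexts (needs `patient_id`, `date`, `ldl`).
#' @param config [cohort_config()].
#' @return Tibble of sequence elements: `patient_id`, `index` (1-based within
#'   sequence), `date`, `ldl`, `state`, `follow_up_type` (`NA` for the first
#'   element); attribute `discards` holds the counts
#'   `c(unrelated = ..., singleton_measurements = ..., singleton_patients = ...)`.
#' @export
link_measurements <- function(contexts, config = cohort_config()) {
  df <- contexts |>
    dplyr::select("patient_id", "date", "ldl") |>
    dplyr::arrange(.data$patient_id, .data$date)
  if (anyDuplicated(df[c("patient_id", "date")]) > 0) {
    stop("link_measurements(): duplicate measurement dates within a patient",
         call. = FALSE)
  }
  if (nrow(df) == 0) {
    out <- tibble::tibble(patient_id = character(),
                          index = integer(), date = as.Date(character()),
                          ldl = double(),
                          state = factor(character(),
                                         levels = ldl_state_levels()),
                          follow_up_type = factor(character(),
                                                  levels = c("SHORT", "LONG")))
    attr(out, "discards") <- c(unrelated = 0L, singleton_measurements = 0L,
                               singleton_patients = 0L)
    return(out)
  }
  code <- greedy_link_cpp(as.integer(factor(df$patient_id,
                                            levels = unique(df$patient_id))),
                          as.integer(df$date),
                          config$short_min_days, config$short_max_days,
                          config$long_max_days)
  n_unrelated <- sum(code == -1L)
  kept <- df[code != -1L, , drop = FALSE]
  kept$follow_up_type <- factor(c(NA, "SHORT", "LONG")[code[code != -1L] + 1L],
                                levels = c("SHORT", "LONG"))
  kept <- kept |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(index = dplyr::row_number(), seq_len = dplyr::n()) |>
    dplyr::ungroup()
  singles <- kept$seq_len < 2
  n_single <- sum(singles)
  out <- kept[!singles, , drop = FALSE] |>
    dplyr::mutate(state = ldl_state(.data$ldl, config$ldl_target)) |>
    dplyr::select("patient_id", "index", "date", "ldl", "state",
                  "follow_up_type")
  attr(out, "discards") <- c(
    unrelated = n_unrelated,
    singleton_measurements = n_single,
    singleton_patients = length(unique(kept$patient_id[singles]))
  )
  out
}

#' Truncate state sequences at a length percentile
#'
#' Computes the nearest-rank percentile `k` of sequence lengths and keeps the
#' first `min(length, k)` elements of every sequence.
#'
#' @param sequences Long-format sequences ([link_measurements()]).
#' @param percentile Percentile of lengths (default from the usual
#'   75th-percentile truncation).
#' @return Truncated sequences with attribute `cutoff` = `k`.
#' @export
truncate_sequences <- function(sequences, percentile = 75) {
  stopifnot(nrow(sequences) > 0)
  lens <- sequences |>
    dplyr::count(.data$patient_id, name = "len")
  k <- nearest_rank(lens$len, percentile)
  out <- dplyr::filter(sequences, .data$index <= k)
  attr(out, "cutoff") <- k
  out
}

#' Empirical transition matrix over LDL-c states
#'
#' Pools every consecutive pair of every sequence at every position (a
#' measurement can be both the second of one pair and the first of the next)
#' and normalizes rows with at least one observed pair — the homogeneous
#' Markov-chain estimate.
#'
#' @param sequences Long-format sequences (length >= 2 per patient).
#' @return List of class `ldl_transition_matrix` with `counts`, `probs`
#'   (rows with zero pairs are `NA`), and `row_totals`.
#' @export
transition_matrix <- function(sequences) {
  lv <- ldl_state_levels()
  df <- dplyr::arrange(sequences, .data$patient_id, .data$index)
  s <- match(as.character(df$state), lv)
  if (anyNA(s)) stop("unknown state label in sequences", call. = FALSE)
  n <- nrow(df)
  if (n >= 2) {
    same <- df$patient_id[-1] == df$patient_id[-n]
    from <- s[-n][same]
    to <- s[-1][same]
  } else {
    from <- to <- integer(0)
  }
  counts <- matrix(tabulate(from + (to - 1L) * 6L, nbins = 36L), 6, 6,
                   dimnames = list(lv, lv))
  row_totals <- rowSums(counts)
  probs <- counts / ifelse(row_totals > 0, row_totals, NA_real_)
  structure(list(counts = counts, probs = probs, row_totals = row_totals),
            class = "ldl_transition_matrix")
}

#' @export
print.ldl_transition_matrix <- function(x, digits = 3, ...) {
  cat("Empirical LDL-c state transition matrix (",
      sum(x$row_totals), " pooled pairs)\n", sep = "")
  print(round(x$probs, digits))
  invisible(x)
}

#' Per-index state distributions
#'
#' For each measurement index `i`, the distribution over the six states among
#' sequences of length at least `i` (the state-distribution plot of a
#' sequence analysis).
#'
#' @param sequences Long-format (typically truncated) sequences.
#' @return Tibble with `index`, `state`, `n`, `proportion`,
#'   `n_sequences` (denominator).
#' @export
state_distributions <- function(sequences) {
  sequences |>
    dplyr::count(.data$index, .data$state, .drop = FALSE, name = "n") |>
    dplyr::group_by(.data$index) |>
    dplyr::mutate(n_sequences = sum(.data$n),
                  proportion = .data$n / .data$n_sequences) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$n_sequences > 0)
}
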