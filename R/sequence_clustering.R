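#' Substitution costs for optimal matching
#'
#' Either a constant cost for every substitution (the conventional default,
#' 2.0 with indel 1.0), or transition-rate (TRATE) costs
#' `cost(i, j) = 2 - P(i -> j) - P(j -> i)` derived from an estimated
#' transition matrix, clipped at zero.
#'
#' @param method `"constant"` or `"trate"`.
#' @param transition Transition matrix object ([transition_matrix()]),
#'   required for `"trate"`.
#' @param constant_value Off-diagonal cost under `"constant"`.
#' @return 6x6 symmetric non-negative matrix with zero diagonal.
#' @export
substitution_costs <- function(method = c("constant", "trate"),
                               transition = NULL, constant_value = 2.0) {
  method <- match.arg(method)
  lv <- ldl_state_levels()
  if (method == "constant") {
    stopifnot(constant_value >= 0)
    costs <- matrix(constant_value, 6, 6, dimnames = list(lv, lv))
    diag(costs) <- 0
    return(costs)
  }
  stopifnot(inherits(transition, "ldl_transition_matrix"))
  if (any(transition$row_totals == 0)) {
    empty <- lv[transition$row_totals == 0]
    stop("substitution_costs(trate): no observed transitions from state(s): ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  p <- transition$probs
  costs <- pmax(2 - p - t(p), 0)
  diag(costs) <- 0
  dimnames(costs) <- list(lv, lv)
  costs
}

# long-format sequences -> named list of integer state vectors
sequences_as_list <- function(sequences) {
  sequences <- dplyr::arrange(sequences, .data$patient_id, .data$index)
  codes <- as.integer(factor(as.character(sequences$state),
                             levels = ldl_state_levels()))
  if (anyNA(codes)) stop("unknown state symbol in sequences", call. = FALSE)
  split(codes, sequences$patient_id)
}

#' Optimal-matching distance between two state sequences
#'
#' Minimum total cost of transforming one sequence into the other by
#' substitutions (costed by `costs`) and insertions/deletions (costed by
#' `indel`), computed by dynamic programming.
#'
#' @param seq_a,seq_b Character/factor vectors of state labels, or integer
#'   state codes (1-6).
#' @param costs Substitution-cost matrix ([substitution_costs()]).
#' @param indel Insertion/deletion cost.
#' @return Non-negative scalar distance.
#' @export
om_distance <- function(seq_a, seq_b, costs = substitution_costs(),
                        indel = 1.0) {
  enc <- function(s) {
    if (is.numeric(s)) return(as.integer(s))
    i <- as.integer(factor(as.character(s), levels = ldl_state_levels()))
    if (anyNA(i)) stop("unknown state symbol", call. = FALSE)
    i
  }
  a <- enc(seq_a); b <- enc(seq_b)
  stopifnot(length(a) >= 1, length(b) >= 1,
            max(a, b) <= nrow(costs), indel > 0)
  om_cost_cpp(a, b, costs, indel)
}

#' Pairwise optimal-matching distance matrix
#'
#' @param sequences Long-format sequences ([truncate_sequences()]).
#' @param costs Substitution-cost matrix.
#' @param indel Insertion/deletion cost.
#' @return Symmetric distance matrix with patient ids as dimnames.
#' @export
pairwise_distances <- function(sequences, costs = substitution_costs(),
                               indel = 1.0) {
  lst <- sequences_as_list(sequences)
  if (length(lst) < 2) stop("need at least two sequences", call. = FALSE)
  d <- om_pairwise_cpp(unname(lst), costs, indel)
  dimnames(d) <- list(names(lst), names(lst))
  d
}

#' Cluster state sequences
#'
#' Agglomerative hierarchical clustering with Ward-type linkage on the
#' optimal-matching dissimilarity matrix (`stats::hclust(method =
#' "ward.D2")`, i.e. the Ward criterion on squared dissimilarities; the input
#' is not Euclidean, which is the usual caveat of Ward on sequence
#' dissimilarities). Cluster labels are deterministic: numbered by size,
#' descending, ties broken by the lowest member id.
#'
#' @param distances Distance matrix ([pairwise_distances()]).
#' @param n_clusters Number of clusters, in `[2, n - 1]`.
#' @return Named integer vector of cluster labels with attributes `summary`
#'   (per-cluster mean off-target share and mean worst state, filled by
#'   [cluster_summaries()] when sequences are supplied there) and `hclust`.
#' @export
cluster_sequences <- function(distances, n_clusters = 4) {
  n <- nrow(distances)
  if (n_clusters < 2 || n_clusters > n - 1) {
    stop("n_clusters must be in [2, n-1]", call. = FALSE)
  }
  hc <- stats::hclust(stats::as.dist(distances), method = "ward.D2")
  raw <- stats::cutree(hc, k = n_clusters)
  sizes <- table(raw)
  first_member <- tapply(seq_along(raw), raw, min)
  ord <- order(-as.integer(sizes), as.integer(first_member))
  relabel <- integer(n_clusters)
  relabel[as.integer(names(sizes))[ord]] <- seq_len(n_clusters)
  labels <- relabel[raw]
  names(labels) <- rownames(distances)
  attr(labels, "hclust") <- hc
  labels
}

#' Per-cluster sequence summaries
#'
#' Mean share of off-target elements and mean worst (maximum) state per
#' cluster, used to identify the worst-trajectory cluster.
#'
#' @param labels Cluster labels ([cluster_sequences()]).
#' @param sequences Long-format sequences the labels were computed from.
#' @return Tibble with `cluster`, `n`, `mean_off_target_share`,
#'   `mean_worst_state`.
#' @export
cluster_summaries <- function(labels, sequences) {
  per_seq <- sequences |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      off_share = mean(.data$state != "ON_TARGET"),
      worst = max(as.integer(.data$state)), .groups = "drop")
  per_seq$cluster <- labels[per_seq$patient_id]
  per_seq |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_off_target_share = mean(.data$off_share),
                     mean_worst_state = mean(.data$worst), .groups = "drop")
}

#' Silhouette width per candidate cluster count
#'
#' Average silhouette width over a range of `k`, to aid choosing the number
#' of clusters (which the method itself does not fix).
#'
#' @param distances Distance matrix.
#' @param k_range Candidate cluster counts.
#' @return Tibble with `k`, `avg_silhouette`.
#' @export
silhouette_by_k <- function(distances, k_range = 2:8) {
  d <- stats::as.dist(distances)
  hc <- stats::hclust(d, method = "ward.D2")
  k_range <- k_range[k_range >= 2 & k_range <= nrow(distances) - 1]
  purrr::map_dfr(k_range, function(k) {
    sil <- cluster::silhouette(stats::cutree(hc, k = k), d)
    tibble::tibble(k = k, avg_silhouette = mean(sil[, "sil_width"]))
  })
}

#' Cluster-membership covariate models
#'
#' One-vs-rest binomial logistic model per cluster: membership of the cluster
#' as outcome, patient covariates at first measurement as explanatory
#' variables; Wald 95\% confidence intervals. Clusters with fewer than
#' `min_members` members are skipped with a warning.
#'
#' @param labels Cluster labels.
#' @param covariates Per-patient covariate tibble (column `patient_id` plus
#'   covariates: `age`, `women`, `diabetes`, `hypertension`, `smoking`,
#'   `statin`, `antithrombotic` — any subset is used as supplied).
#' @param min_members Minimum cluster size to model.
#' @return Tibble of odds ratios with a `cluster` column.
#' @export
cluster_covariate_model <- function(labels, covariates, min_members = 10) {
  stopifnot("patient_id" %in% names(covariates))
  df <- covariates[match(names(labels), covariates$patient_id), ,
                   drop = FALSE]
  df$cluster <- as.integer(labels)
  df <- stats::na.omit(df)
  terms <- setdiff(names(covariates), "patient_id")
  out <- purrr::map_dfr(sort(unique(df$cluster)), function(cl) {
    if (sum(df$cluster == cl) < min_members) {
      warning("cluster ", cl, " has fewer than ", min_members,
              " members; model skipped", call. = FALSE)
      return(tibble::tibble())
    }
    dat <- df
    dat$in_cluster <- dat$cluster == cl
    fit <- stats::glm(
      stats::reformulate(terms, response = "in_cluster"),
      family = stats::binomial(), data = dat)
    dplyr::mutate(wald_or_table(fit), cluster = cl, .before = 1)
  })
  out
}
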