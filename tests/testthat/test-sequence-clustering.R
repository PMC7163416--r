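test_that("substitution costs: constant and transition-rate variants", {
  cc <- substitution_costs("constant", constant_value = 2)
  expect_true(all(cc[upper.tri(cc)] == 2))
  expect_true(all(diag(cc) == 0))

  probs <- matrix(0.1, 6, 6)
  diag(probs) <- 0.5
  probs[1, 2] <- 0.10; probs[2, 1] <- 0.30
  probs <- probs / rowSums(probs) * rowSums(probs) # keep as-is
  tm <- structure(list(probs = probs, counts = probs * 100,
                       row_totals = rep(100, 6)),
                  class = "ldl_transition_matrix")
  tc <- substitution_costs("trate", tm)
  expect_equal(tc[1, 2], 2 - 0.10 - 0.30)
  expect_equal(tc, t(tc))
  expect_true(all(diag(tc) == 0))
  # perfectly exchanged states cost nothing
  probs2 <- probs; probs2[1, 2] <- 1; probs2[2, 1] <- 1
  tm2 <- structure(list(probs = probs2, counts = probs2,
                        row_totals = rep(1, 6)),
                   class = "ldl_transition_matrix")
  expect_equal(substitution_costs("trate", tm2)[1, 2], 0)
  tm3 <- tm
  tm3$row_totals[3] <- 0
  expect_error(substitution_costs("trate", tm3), "OFF_0_5_0_9")
})

test_that("optimal matching handles the hand-checked base cases", {
  costs <- substitution_costs("constant", constant_value = 2)
  a <- c("ON_TARGET", "OFF_LT_0_5")
  expect_equal(om_distance(a, a, costs), 0)
  expect_equal(om_distance("ON_TARGET", c("ON_TARGET", "OFF_LT_0_5"),
                           costs, indel = 1), 1)
  expect_equal(om_distance(c("ON_TARGET", "OFF_LT_0_5"),
                           c("ON_TARGET", "ON_TARGET"), costs, indel = 1), 2)
  expect_error(om_distance("NOT_A_STATE", "ON_TARGET", costs), "unknown")
})

test_that("optimal matching equals the exhaustive alignment oracle", {
  set.seed(31)
  sub <- matrix(c(0, 1, 2,
                  1, 0, 1.5,
                  2, 1.5, 0), 3, 3, byrow = TRUE)
  for (i in 1:20) {
    a <- sample.int(3, sample.int(4, 1), replace = TRUE)
    b <- sample.int(3, sample.int(4, 1), replace = TRUE)
    expect_equal(om_distance(a, b, sub, indel = 1),
                 om_oracle(a, b, sub, indel = 1),
                 label = paste(paste(a, collapse = ""),
                               paste(b, collapse = "")))
  }
})

test_that("optimal matching is a bounded pseudo-metric under constant costs", {
  set.seed(32)
  costs <- substitution_costs("constant", constant_value = 2)
  rand_seq <- function() sample.int(6, sample(2:6, 1), replace = TRUE)
  for (i in 1:30) {
    a <- rand_seq(); b <- rand_seq(); c <- rand_seq()
    dab <- om_distance(a, b, costs)
    dba <- om_distance(b, a, costs)
    dac <- om_distance(a, c, costs)
    dcb <- om_distance(c, b, costs)
    expect_equal(dab, dba)
    expect_lte(dab, dac + dcb + 1e-12)
    expect_lte(dab, 1.0 * (length(a) + length(b)))
    expect_gte(dab, 0)
  }
})

test_that("equal-length distances are bounded by the Hamming substitution path", {
  # with sub cost <= 2*indel the all-substitution alignment is feasible, so
  # the optimum never exceeds c * Hamming (shifted alignments may beat it,
  # e.g. AB vs BA via one deletion and one insertion)
  set.seed(33)
  costs <- substitution_costs("constant", constant_value = 1.5)
  for (i in 1:20) {
    len <- sample(2:6, 1)
    a <- sample.int(6, len, replace = TRUE)
    b <- sample.int(6, len, replace = TRUE)
    d <- om_distance(a, b, costs, indel = 1)
    expect_lte(d, 1.5 * sum(a != b))
    expect_equal(d == 0, all(a == b))
    if (sum(a != b) == 1) expect_equal(d, 1.5)
  }
  expect_equal(om_distance(c(1, 2), c(2, 1),
                           substitution_costs("constant", 2), indel = 1), 2)
})

test_that("pairwise distances are symmetric and permutation-consistent", {
  seqs <- mk_sequences(list(c("ON_TARGET", "ON_TARGET"),
                            c("ON_TARGET", "ON_TARGET"),
                            c("OFF_GE_2_0", "OFF_1_5_1_9", "OFF_GE_2_0")))
  d <- pairwise_distances(seqs)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_equal(d["SEQ001", "SEQ002"], 0)
  # permuting input rows permutes the matrix consistently
  seqs_perm <- dplyr::arrange(seqs, dplyr::desc(patient_id))
  d2 <- pairwise_distances(seqs_perm)
  expect_equal(d2[rownames(d), colnames(d)], d)
})

test_that("well-separated bundles cluster perfectly and duplicates co-cluster", {
  states <- c(rep(list(rep("ON_TARGET", 4)), 6),
              rep(list(rep("OFF_GE_2_0", 4)), 4))
  seqs <- mk_sequences(states)
  d <- pairwise_distances(seqs)
  labels <- cluster_sequences(d, 2)
  on_ids <- sprintf("SEQ%03d", 1:6)
  expect_equal(length(unique(labels[on_ids])), 1)
  expect_equal(length(unique(labels[setdiff(names(labels), on_ids)])), 1)
  # labels are numbered by size: the on-target bundle (6 members) is cluster 1
  expect_equal(unname(labels[on_ids[1]]), 1L)
  summ <- cluster_summaries(labels, seqs)
  expect_equal(summ$mean_off_target_share, c(0, 1))
  # k = n-1 merges exactly one pair (the zero-distance duplicates)
  lab_n1 <- cluster_sequences(d, nrow(d) - 1)
  expect_equal(sort(unname(table(lab_n1)), decreasing = TRUE)[1], 2L)
  expect_error(cluster_sequences(d, 1), "n_clusters")
  expect_error(cluster_sequences(d, nrow(d)), "n_clusters")
})

test_that("silhouette report covers the requested k grid", {
  states <- c(rep(list(rep("ON_TARGET", 3)), 5),
              rep(list(rep("OFF_GE_2_0", 3)), 5),
              rep(list(c("ON_TARGET", "OFF_GE_2_0", "ON_TARGET")), 5))
  d <- pairwise_distances(mk_sequences(states))
  sil <- silhouette_by_k(d, 2:5)
  expect_equal(sil$k, 2:5)
  expect_true(all(sil$avg_silhouette >= -1 & sil$avg_silhouette <= 1))
})

test_that("cluster covariate model matches the 2x2 closed form", {
  labels <- c(rep(1L, 100), rep(2L, 100))
  names(labels) <- sprintf("P%03d", 1:200)
  # women: 60/100 in cluster 1, 30/100 in cluster 2
  covars <- tibble::tibble(
    patient_id = names(labels),
    women = c(rep(TRUE, 60), rep(FALSE, 40), rep(TRUE, 30), rep(FALSE, 70)))
  out <- cluster_covariate_model(labels, covars)
  or1 <- unname(out$or[out$cluster == 1 & out$term == "womenTRUE"])
  expect_equal(or1, (60 * 70) / (40 * 30), tolerance = 1e-6)
  # one-vs-rest symmetry for two clusters
  or2 <- unname(out$or[out$cluster == 2 & out$term == "womenTRUE"])
  expect_equal(or2, 1 / or1, tolerance = 1e-6)
  # small clusters are skipped with a warning
  labels2 <- c(rep(1L, 195), rep(2L, 5))
  names(labels2) <- covars$patient_id
  expect_warning(out2 <- cluster_covariate_model(labels2, covars),
                 "fewer than")
  expect_true(all(out2$cluster == 1))
})

test_that("the worst-trajectory cluster is enriched for women under the generator", {
  cohort <- generate_cohort(generator_config(n_patients = 4000, seed = 33))
  tb <- cohort$tables
  ctx <- build_contexts(
    apply_reliability_filter(assemble_panels(tb$labs))$retained,
    tb$patients, tb$diagnoses, tb$prescriptions, bp = tb$bp,
    smoking = tb$smoking, labs = tb$labs)
  truncated <- truncate_sequences(link_measurements(ctx), 75)
  labels <- cluster_sequences(pairwise_distances(truncated), 4)
  summ <- cluster_summaries(labels, truncated)
  worst <- summ$cluster[which.max(summ$mean_off_target_share)]
  firsts <- ctx[!duplicated(ctx$patient_id), ]
  covars <- tibble::tibble(patient_id = firsts$patient_id,
                           women = firsts$sex == "female")
  ors <- suppressWarnings(cluster_covariate_model(labels, covars))
  worst_or <- ors$or[ors$cluster == worst & ors$term == "womenTRUE"]
  # women deteriorate more often (generator tilt log 1.44), so the cluster
  # with the most off-target measurements should over-represent them
  expect_gt(worst_or, 1)
})
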