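test_that("follow-up classification matches the month windows", {
  expect_equal(as.character(classify_follow_up(c(90, 365, 30, 600))),
               c("SHORT", "LONG", "UNRELATED", "UNRELATED"))
  # boundaries: lower window wins at the shared 6-month edge
  expect_equal(as.character(classify_follow_up(c(61, 183, 184, 548, 549))),
               c("SHORT", "SHORT", "LONG", "LONG", "UNRELATED"))
  expect_error(classify_follow_up(0), "non-positive")
})

test_that("the three follow-up classes partition all positive gaps", {
  f <- classify_follow_up(1:1000)
  expect_false(anyNA(f))
  expect_equal(sum(table(f)), 1000)
})

test_that("greedy linking re-anchors on the last retained measurement", {
  # all related: intervals [90, 90]
  ctx <- mk_contexts("P1", as.Date("2010-01-01") + c(0, 90, 180), 2.0)
  seqs <- link_measurements(ctx)
  expect_equal(nrow(seqs), 3)
  expect_equal(as.character(seqs$follow_up_type), c(NA, "SHORT", "SHORT"))

  # intervals [30, 60]: second unrelated to first (30 d), third related to
  # the FIRST retained (90 d), not to the discarded second
  ctx2 <- mk_contexts("P2", as.Date("2010-01-01") + c(0, 30, 90), 2.0)
  seqs2 <- link_measurements(ctx2)
  expect_equal(nrow(seqs2), 2)
  expect_equal(seqs2$date, as.Date("2010-01-01") + c(0, 90))
  expect_equal(unname(attr(seqs2, "discards")[["unrelated"]]), 1L)

  # a single measurement yields no sequence and is counted
  seqs3 <- link_measurements(mk_contexts("P3", "2010-01-01", 2.0))
  expect_equal(nrow(seqs3), 0)
  expect_equal(unname(attr(seqs3, "discards")[["singleton_patients"]]), 1L)
})

test_that("linking conserves measurements on a generated cohort", {
  cohort <- generate_cohort(generator_config(n_patients = 800, seed = 17))
  tb <- cohort$tables
  ctx <- build_contexts(
    apply_reliability_filter(assemble_panels(tb$labs))$retained,
    tb$patients, tb$diagnoses, tb$prescriptions, bp = tb$bp,
    smoking = tb$smoking, labs = tb$labs)
  seqs <- link_measurements(ctx)
  disc <- attr(seqs, "discards")
  expect_equal(nrow(seqs) + unname(disc[["unrelated"]]) +
                 unname(disc[["singleton_measurements"]]), nrow(ctx))
  # generator truth and pipeline agree on which follow-ups are related
  truth_fu <- cohort$truth$measurements[cohort$truth$measurements$index > 1, ]
  expect_equal(unname(disc[["unrelated"]]), sum(!truth_fu$related))
})

test_that("truncation uses the nearest-rank percentile of lengths", {
  seqs <- mk_sequences(list(rep("ON_TARGET", 2), rep("ON_TARGET", 2),
                            rep("ON_TARGET", 3), rep("ON_TARGET", 6),
                            rep("OFF_GE_2_0", 8)))
  tr <- truncate_sequences(seqs, 75)
  expect_equal(attr(tr, "cutoff"), 6)
  expect_equal(max(tr$index[tr$patient_id == "SEQ005"]), 6)
  # 100th percentile: no truncation
  tr100 <- truncate_sequences(seqs, 100)
  expect_equal(nrow(tr100), nrow(seqs))
  # equal lengths: unchanged
  eq <- mk_sequences(list(rep("ON_TARGET", 3), rep("OFF_LT_0_5", 3)))
  expect_equal(nrow(truncate_sequences(eq, 75)), nrow(eq))
})

test_that("transition matrix pools consecutive pairs at every position", {
  one <- mk_sequences(list(rep("ON_TARGET", 3)))
  tm1 <- transition_matrix(one)
  expect_equal(tm1$probs["ON_TARGET", "ON_TARGET"], 1)
  expect_equal(unname(tm1$row_totals[["ON_TARGET"]]), 2)

  two <- mk_sequences(list(c("ON_TARGET", "OFF_LT_0_5"),
                           c("ON_TARGET", "ON_TARGET")))
  tm2 <- transition_matrix(two)
  expect_equal(tm2$probs["ON_TARGET", "ON_TARGET"], 0.5)
  expect_equal(tm2$probs["ON_TARGET", "OFF_LT_0_5"], 0.5)
  # rows with no pairs are NA, populated rows are stochastic
  expect_true(all(is.na(tm2$probs["OFF_GE_2_0", ])))
  expect_equal(sum(tm2$probs["ON_TARGET", ]), 1, tolerance = 1e-9)
})

test_that("populated transition rows are stochastic on simulated data", {
  seqs <- simulate_state_sequences(300, generator_config(seed = 2))
  tm <- transition_matrix(seqs)
  pop <- tm$row_totals > 0
  expect_true(all(abs(rowSums(tm$probs[pop, , drop = FALSE]) - 1) < 1e-9))
  expect_equal(sum(tm$counts), sum(tm$row_totals))
})

test_that("state distributions are per-index and properly normalized", {
  seqs <- mk_sequences(list(c("ON_TARGET", "OFF_LT_0_5", "ON_TARGET"),
                            c("ON_TARGET", "ON_TARGET")))
  sd <- state_distributions(seqs)
  idx1 <- sd[sd$index == 1, ]
  expect_equal(idx1$proportion[idx1$state == "ON_TARGET"], 1)
  # denominator: sequences of length >= i
  expect_equal(unique(sd$n_sequences[sd$index == 3]), 1)
  expect_equal(unique(sd$n_sequences[sd$index == 1]), 2)
  sums <- tapply(sd$proportion, sd$index, sum)
  expect_equal(as.numeric(sums), rep(1, 3))
})

test_that("a stationary chain keeps its state distribution across indices", {
  g0 <- generator_config(seed = 6)
  pi_stat <- expected_estimates(
    structure(list(config = g0,
                   patients = tibble::tibble(p_offtarget = numeric(0)),
                   measurements = tibble::tibble(
                     patient_id = character(0), index = integer(0),
                     state = integer(0), related = logical(0))),
              class = "ldl_synthetic_truth"))$stationary_distribution
  g <- generator_config(seed = 6, initial_state_distribution = unname(pi_stat))
  seqs <- simulate_state_sequences(8000, g)
  sd <- state_distributions(seqs)
  for (i in c(1, 3)) {
    di <- sd[sd$index == i, ]
    n <- unique(di$n_sequences)
    se <- sqrt(pi_stat * (1 - pi_stat) / n)
    expect_true(all(abs(di$proportion - pi_stat) < 3 * se),
                label = paste("index", i))
  }
})
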