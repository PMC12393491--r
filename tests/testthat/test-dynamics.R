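test_that("run lengths enumerate maximal constant runs and conserve frames", {
  r <- run_lengths(c(1L, 1L, 1L))
  expect_identical(r$state, 1L)
  expect_identical(r$length, 3L)
  r2 <- run_lengths(c(1L, 1L, 2L, 2L, 2L, 1L))
  expect_identical(r2$state, c(1L, 2L, 1L))
  expect_identical(r2$length, c(2L, 3L, 1L))
  set.seed(8)
  lab <- sample.int(4L, 1000L, replace = TRUE)
  expect_identical(sum(run_lengths(lab)$length), 1000L)
})

test_that("dwell time is mean run length times TR; unvisited states are NA", {
  sq <- state_sequence("a", rep(2L, 10L), 4L, 2.1)
  dt <- dwell_time(sq)
  expect_equal(dt[2L], 21.0)
  expect_true(all(is.na(dt[c(1L, 3L, 4L)])))
  # runs (2,1) for state 1 -> mean 1.5 frames; run (3) for state 2
  sq2 <- state_sequence("b", c(1L, 1L, 2L, 2L, 2L, 1L), 2L, 2)
  expect_equal(dwell_time(sq2), c(3.0, 6.0))
})

test_that("dwell time follows the geometric run-length law", {
  for (p_self in c(0.6, 0.85)) {
    P <- matrix((1 - p_self) / 3, 4L, 4L)
    diag(P) <- p_self
    s <- simulate_state_sequence(P, 50000L, seed = 17L)
    dt <- dwell_time(state_sequence("x", s, 4L, 2.1))
    expect_equal(mean(dt), 2.1 / (1 - p_self), tolerance = 0.05)
  }
})

test_that("fractional occupancy is a percentage summing to 100", {
  expect_equal(fractional_occupancy(state_sequence("a", rep(1L, 5L), 4L, 2)),
               c(100, 0, 0, 0))
  expect_equal(fractional_occupancy(state_sequence("a", c(1L, 2L, 1L, 2L),
                                                   2L, 2)), c(50, 50))
  P <- matrix(0.25, 4L, 4L)
  s <- simulate_state_sequence(P, 100000L, seed = 21L)
  fo <- fractional_occupancy(state_sequence("a", s, 4L, 2))
  expect_equal(sum(fo), 100, tolerance = 1e-9)
  expect_true(all(abs(fo - 25) < 1))
})

test_that("transition probabilities count switches under joint normalization", {
  sq <- state_sequence("a", c(1L, 2L, 1L, 3L, 1L, 2L), 3L, 2)
  p <- transition_probabilities(sq)
  expect_equal(p[1L, 2L], 0.4)
  expect_equal(p[2L, 1L], 0.2)
  expect_equal(p[1L, 3L], 0.2)
  expect_equal(p[3L, 1L], 0.2)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_identical(unname(diag(p)), rep(0, 3L))
  expect_identical(attr(p, "n_switches"), 5L)
  # exit/enter from the same counted matrix
  expect_equal(exit_probability(p, 1L), 0.3)
  expect_equal(enter_probability(p, 1L), (0.2 + 0.2) / 2)
  # alternating sequence with equal switch counts: symmetric halves
  pa <- transition_probabilities(state_sequence("b",
                                                c(rep(c(1L, 2L), 10L), 1L),
                                                2L, 2))
  expect_equal(pa[1L, 2L], 0.5, tolerance = 1e-12)
  expect_equal(pa[2L, 1L], 0.5, tolerance = 1e-12)
})

test_that("row normalization makes every exit probability 1/(K-1)", {
  sq <- state_sequence("a", c(1L, 2L, 1L, 3L, 1L, 2L, 3L, 2L), 3L, 2)
  pr <- transition_probabilities(sq, normalize = "row")
  expect_equal(unname(exit_probability(pr)), rep(1 / 2, 3L))
  # whereas joint normalization differentiates states
  pj <- transition_probabilities(sq)
  expect_gt(stats::var(exit_probability(pj)), 0)
})

test_that("constant sequences yield a flagged all-zero matrix", {
  p <- transition_probabilities(state_sequence("a", rep(2L, 6L), 3L, 2))
  expect_true(attr(p, "no_switches"))
  expect_true(all(p == 0))
  expect_equal(enter_probability(p, 1L), 0)
})

test_that("per-subject computation never crosses concatenation boundaries", {
  a <- c(1L, 1L, 2L, 2L)
  b <- c(3L, 3L, 1L, 1L)
  sol <- list(k = 3L, labels = c(a, b))
  class(sol) <- "cluster_solution"
  ds <- list(frame_subject_index = rep(c("a", "b"), each = 4L),
             tr_seconds = 2)
  class(ds) <- "concatenated_dataset"
  seqs <- split_state_sequences(sol, ds)
  pa <- transition_probabilities(seqs[["a"]])
  pb <- transition_probabilities(seqs[["b"]])
  # the 2 -> 3 pair spans the boundary and must not be counted
  expect_equal(pa[2L, 3L], 0)
  expect_equal(pb[2L, 3L], 0)
  expect_equal(pa[1L, 2L], 1)
  expect_equal(pb[3L, 1L], 1)
  # identical to computing on each subject separately
  expect_identical(unclass(pa),
                   unclass(transition_probabilities(
                     state_sequence("a", a, 3L, 2))))
})

test_that("occupancy identity: visits x mean run length / T", {
  set.seed(31)
  lab <- simulate_state_sequence(default_group_transitions(4L)$HC, 500L,
                                 seed = 31L)
  sq <- state_sequence("a", lab, 4L, 2.1)
  fo <- fractional_occupancy(sq)
  r <- run_lengths(lab)
  for (s in 1:4) {
    runs <- r$length[r$state == s]
    expect_equal(fo[s] / 100, length(runs) * mean(runs) / length(lab),
                 tolerance = 1e-12)
  }
})

test_that("run-permutation null flags planted pair preferences", {
  # strong 1 -> 2 preference
  P <- matrix(c(0.6, 0.35, 0.05,
                0.1, 0.6, 0.3,
                0.3, 0.1, 0.6), 3L, 3L, byrow = TRUE)
  s <- simulate_state_sequence(P, 2000L, seed = 41L)
  res <- permutation_null_transitions(state_sequence("a", s, 3L, 2),
                                      n_perm = 1000L, seed = 5L)
  expect_false(res$skipped)
  expect_lt(res$p_values[1L, 2L], 0.05)
  # null preserves run-length multiset: occupancies unchanged
  expect_equal(rowSums(res$null_mean), rowSums(res$observed),
               tolerance = 0.05)
})

test_that("permutation null is calibrated on exchangeable sequences", {
  # few-run sequences are skipped; tiny n_perm is an error
  short <- state_sequence("a", c(1L, 1L, 2L), 2L, 2)
  expect_true(permutation_null_transitions(short, n_perm = 100L)$skipped)
  expect_error(permutation_null_transitions(short, n_perm = 0L), "n_perm")
  # under a uniform chain, p-values should not pile up near 0
  P <- matrix(1 / 3, 3L, 3L)
  pvals <- c()
  for (seed in 1:20) {
    s <- simulate_state_sequence(P, 300L, seed = 100L + seed)
    res <- permutation_null_transitions(state_sequence("a", s, 3L, 2),
                                        n_perm = 199L, seed = seed)
    pvals <- c(pvals, res$p_values[upper.tri(res$p_values)])
  }
  expect_gt(mean(pvals), 0.3)
  expect_lt(mean(pvals < 0.05), 0.12)
})

test_that("cohort dynamics table is complete and conserved per subject", {
  cfg <- small_config(seed = 19L, subjects = 2L, frames = 80L)
  coh <- generate_cohort(cfg)
  seqs <- lapply(names(coh$ground_truth$state_sequences), function(id) {
    state_sequence(id, coh$ground_truth$state_sequences[[id]], 4L, 2.1)
  })
  names(seqs) <- names(coh$ground_truth$state_sequences)
  dyn <- cohort_dynamics(seqs)
  for (id in names(seqs)) {
    fo <- dyn$value[dyn$subject == id & dyn$metric == "fractional_occupancy"]
    expect_equal(sum(fo), 100, tolerance = 1e-9)
    tp <- dyn$value[dyn$subject == id & dyn$metric == "transition_probability"]
    expect_equal(sum(tp), 1, tolerance = 1e-12)
  }
})
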