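test_that("planted state patterns are z-scored, separable and deterministic", {
  parc <- default_parcellation(85L)
  cent <- generate_state_patterns(4L, 85L, parc, seed = 7L)
  expect_equal(dim(cent), c(4L, 85L))
  expect_true(all(abs(rowMeans(cent)) < 1e-9))
  expect_true(all(abs(sqrt(rowMeans(cent^2)) - 1) < 1e-9))
  cc <- cor(t(cent))
  expect_true(all(cc[upper.tri(cc)] < 0.3))
  expect_identical(cent, generate_state_patterns(4L, 85L, parc, seed = 7L))
  expect_false(identical(cent, generate_state_patterns(4L, 85L, parc, seed = 8L)))
})

test_that("two states over two disjoint networks are antisymmetric", {
  parc <- default_parcellation(4L, c("VIS", "DMN"))
  cent <- generate_state_patterns(2L, 4L, parc, seed = 1L, jitter_sd = 0)
  expect_equal(cor(cent[1L, ], cent[2L, ]), -1, tolerance = 1e-12)
})

test_that("pattern generation fails on infeasible separation", {
  expect_error(generate_state_patterns(4L, 6L, default_parcellation(6L)),
               "infeasible")
  parc <- default_parcellation(20L, c("VIS", "DMN"))
  expect_error(generate_state_patterns(3L, 20L, parc), "infeasible")
})

test_that("Markov sequences respect the transition law", {
  # 2-state symmetric chain: empirical switch rate equals off-diagonal mass
  p2 <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  s <- simulate_state_sequence(p2, 100000L, seed = 3L)
  expect_lt(abs(mean(diff(s) != 0) - 0.1), 0.005)
  # uniform 4-state chain: 25% occupancy each
  p4 <- matrix(0.25, 4, 4)
  s4 <- simulate_state_sequence(p4, 100000L, seed = 4L)
  occ <- tabulate(s4, 4L) / length(s4)
  expect_true(all(abs(occ - 0.25) < 0.01))
  # absorbing identity chain: constant
  sid <- simulate_state_sequence(diag(3), 50L, seed = 5L)
  expect_length(unique(sid), 1L)
  # non-stochastic rows rejected
  expect_error(simulate_state_sequence(matrix(c(0.5, 0.4, 0.1, 0.9), 2, 2,
                                              byrow = TRUE), 10L),
               "sums to")
})

test_that("empirical transition matrix converges to the specified one", {
  P <- default_group_transitions(4L)$HC
  s <- simulate_state_sequence(P, 10000L, seed = 11L)
  emp <- empirical_transition_matrix(s, 4L)
  expect_lt(max(abs(emp - P)), 0.03)
})

test_that("emitted BOLD equals centroids exactly at zero noise", {
  toy <- toy_two_state_series(noise_sd = 0)
  ts <- emit_bold(toy$labels, toy$centroids, 0.45, 0, seed = 1L)
  expect_equal(ts$matrix, t(toy$centroids)[, toy$labels],
               ignore_attr = TRUE, tolerance = 0)
})

test_that("AR(1) noise has the requested lag-1 autocorrelation", {
  parc <- default_parcellation(8L)
  cent <- generate_state_patterns(2L, 8L, parc, seed = 2L)
  labels <- rep(1L, 20000L)
  for (phi in c(0, 0.5)) {
    ts <- emit_bold(labels, cent, phi, 1, seed = 6L)
    resid <- ts$matrix - t(cent)[, labels]
    ac <- mean(apply(resid, 1L, function(e) {
      cor(e[-length(e)], e[-1L])
    }))
    expect_equal(ac, phi, tolerance = 0.02)
  }
  expect_error(emit_bold(labels, cent, 1, 1), "phi")
})

test_that("emitted per-ROI variance matches the AR(1) + switching law", {
  parc <- default_parcellation(10L)
  cent <- generate_state_patterns(2L, 10L, parc, seed = 3L)
  P <- matrix(c(0.7, 0.3, 0.3, 0.7), 2, 2)
  labels <- simulate_state_sequence(P, 30000L, seed = 4L)
  phi <- 0.45
  ts <- emit_bold(labels, cent, phi, 0.8, seed = 5L)
  noise_var <- 0.8^2 / (1 - phi^2)
  # stationary occupancy is 50/50, so switching variance per ROI is the
  # variance of the two centroid values
  switch_var <- apply(cent, 2L, function(v) mean(v^2) - mean(v)^2)
  expect_equal(apply(ts$matrix, 1L, var), noise_var + switch_var,
               tolerance = 0.1, ignore_attr = TRUE)
})

test_that("synthetic connectomes are symmetric, hollow, modular, connected", {
  parc <- default_parcellation(30L, c("VIS", "SOM", "DMN"))
  cn <- generate_connectome(30L, parc, seed = 3L)
  a <- cn$weights
  expect_identical(max(abs(a - t(a))), 0)
  expect_identical(unname(diag(a)), rep(0, 30L))
  expect_true(all(a >= 0))
  same <- outer(parc$network, parc$network, "==")
  ut <- upper.tri(a)
  expect_gt(mean(a[ut & same]), mean(a[ut & !same]))
  # 2-node case: the single off-diagonal weight is positive
  c2 <- generate_connectome(2L, seed = 1L)
  expect_gt(c2$weights[1L, 2L], 0)
})

test_that("clinical scores track planted occupancy as configured", {
  strong <- small_config(seed = 9L, subjects = 20L,
                         clinical_coupling = c(QIDS = 3), clinical_noise_sd = 0.5)
  coh <- generate_cohort(strong)
  expect_gt(cor(coh$clinical$QIDS, coh$ground_truth$planted_occupancy), 0.9)
  none <- small_config(seed = 9L, subjects = 38L,
                       clinical_coupling = c(QIDS = 0), clinical_noise_sd = 2)
  coh0 <- generate_cohort(none)
  expect_lt(abs(cor(coh0$clinical$QIDS, coh0$ground_truth$planted_occupancy)),
            0.25)
})

test_that("cohort generation is deterministic and written bundles reproduce", {
  cfg <- small_config(seed = 21L, subjects = 2L, frames = 40L, n_rois = 12L)
  d1 <- file.path(tempdir(), "cohA")
  d2 <- file.path(tempdir(), "cohB")
  write_cohort(generate_cohort(cfg), d1)
  write_cohort(generate_cohort(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("planted group differences are recovered with the planted sign", {
  cfg <- synthetic_config(seed = 31L)
  coh <- generate_cohort(cfg)
  seqs <- lapply(names(coh$ground_truth$state_sequences), function(id) {
    state_sequence(id, coh$ground_truth$state_sequences[[id]], 4L, 2.1)
  })
  names(seqs) <- names(coh$ground_truth$state_sequences)
  tests <- compare_groups(cohort_dynamics(seqs), coh$clinical)
  t14 <- tests[tests$metric == "transition_probability" &
                 tests$from_state == 1L & tests$to_state == 4L, ]
  t23 <- tests[tests$metric == "transition_probability" &
                 tests$from_state == 2L & tests$to_state == 3L, ]
  expect_gt(t14$mean_difference, 0)   # HC switches 1 -> 4 more
  expect_lt(t23$mean_difference, 0)   # MDD switches 2 -> 3 more
  expect_lt(t14$p, 0.05)
  expect_lt(t23$p, 0.05)
})
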