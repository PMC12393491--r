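test_that("correlation distance matches the Pearson formula", {
  expect_equal(correlation_distance(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0)
  expect_equal(correlation_distance(c(1, 2, 3, 4), -c(1, 2, 3, 4)), 2)
  # hand Pearson: cov 6.5, sds sqrt(5), sqrt(8.75) => r = 0.9827077
  expect_equal(correlation_distance(c(1, 2, 3, 4), c(1, 2, 3, 5)),
               1 - 6.5 / sqrt(5 * 8.75), tolerance = 1e-12)
  expect_equal(correlation_distance(c(1, 2, 3, 4), c(1, 2, 3, 5)),
               0.01729237, tolerance = 1e-7)
  expect_error(correlation_distance(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("well-separated planted states are recovered exactly", {
  toy <- toy_two_state_series(noise_sd = 1e-4, seed = 3L)
  sol <- kmedoids(toy$ts$matrix, 2L, n_restarts = 3L, seed = 1L)
  m <- match_states(sol$mean_centroids, toy$centroids)
  relabel <- m$permutation[sol$labels]
  expect_identical(relabel, toy$labels)
  expect_true(all(m$matched_correlations > 0.999))
})

test_that("PAM attains the exhaustive-search optimum on small instances", {
  for (seed in 1:4) {
    set.seed(seed)
    t_n <- sample(8:12, 1L)
    x <- matrix(rnorm(5L * t_n), 5L, t_n)
    k <- sample(2:3, 1L)
    sol <- kmedoids(x, k, n_restarts = 5L, seed = seed)
    expect_equal(sol$total_within_distance,
                 brute_force_kmedoids_objective(x, k), tolerance = 1e-9)
  }
})

test_that("PAM matches cluster::pam on the same distance matrix", {
  skip_if_not_installed("cluster")
  set.seed(5)
  x <- matrix(rnorm(6L * 60L), 6L, 60L)
  d <- capdyn:::cor_distance_matrix(x)
  ours <- kmedoids(x, 3L, n_restarts = 5L, seed = 2L)
  ref <- cluster::pam(stats::as.dist(d), k = 3L)
  ref_obj <- sum(apply(d[, ref$id.med, drop = FALSE], 1L, min))
  expect_lte(ours$total_within_distance, ref_obj + 1e-9)
})

test_that("solution invariants hold: medoid membership, label range", {
  cfg <- small_config(seed = 2L)
  ds <- concatenate_cohort(lapply(generate_cohort(cfg)$time_series,
                                  normalize_subject))
  sol <- kmedoids(ds, 4L, n_restarts = 3L, seed = 1L)
  expect_true(all(sol$labels %in% 1:4))
  expect_identical(sol$labels[sol$medoid_frame_indices], 1:4)
  for (c in 1:4) {
    members <- which(sol$labels == c)
    expect_equal(sol$mean_centroids[c, ],
                 rowMeans(ds$matrix[, members, drop = FALSE]),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("clustering is invariant to frame order", {
  toy <- toy_two_state_series(n_rois = 10L, frames = 40L, noise_sd = 0.3,
                              seed = 6L)
  x <- toy$ts$matrix
  sol1 <- kmedoids(x, 2L, n_restarts = 1L, seed = 1L)
  set.seed(99)
  perm <- sample.int(ncol(x))
  sol2 <- kmedoids(x[, perm], 2L, n_restarts = 1L, seed = 1L)
  m <- match_states(sol1$mean_centroids, sol2$mean_centroids)
  expect_identical(m$permutation[sol1$labels], sol2$labels[order(perm)])
  expect_equal(sol1$total_within_distance, sol2$total_within_distance,
               tolerance = 1e-9)
})

test_that("the alternate large-T path agrees with PAM on moderate data", {
  toy <- toy_two_state_series(n_rois = 10L, frames = 300L, noise_sd = 0.5,
                              seed = 8L)
  pam <- kmedoids(toy$ts$matrix, 2L, n_restarts = 3L, seed = 1L,
                  method = "pam")
  alt <- kmedoids(toy$ts$matrix, 2L, n_restarts = 3L, seed = 1L,
                  method = "alternate", sample_size = 100L)
  expect_equal(alt$total_within_distance, pam$total_within_distance,
               tolerance = 0.01)
})

test_that("explained variance behaves at its boundary cases", {
  set.seed(4)
  x <- matrix(rnorm(4L * 6L), 4L, 6L)
  # every frame its own medoid: EV = 1
  sol_t <- kmedoids(x, 5L, n_restarts = 2L, seed = 1L)
  solist <- sol_t
  solist$medoid_frame_indices <- 1:6
  solist$labels <- 1:6
  solist$k <- 6L
  expect_equal(explained_variance(x, solist), 1)
  # hand-computed sums for a 2-medoid solution on 6 frames
  sol2 <- kmedoids(x, 2L, n_restarts = 3L, seed = 1L)
  d <- capdyn:::cor_distance_matrix(x)
  num <- sum(d[cbind(1:6, sol2$medoid_frame_indices[sol2$labels])]^2)
  den <- min(colSums(d^2))
  expect_equal(explained_variance(x, sol2), 1 - num / den, tolerance = 1e-9)
})

test_that("variance gain reads consecutive report rows", {
  rep_df <- data.frame(k = 2:4, explained_variance = c(0.2, 0.5, 0.6))
  expect_equal(variance_gain(rep_df, 3L), 0.3)
  expect_true(is.na(variance_gain(rep_df, 2L)))
})

test_that("medoid silhouette matches hand evaluation on a toy set", {
  # 2 medoids; frames at known distances
  x <- cbind(c(1, 0, 0, 0.5), c(0, 1, 0.5, 0), c(1, 0.1, 0, 0.45),
             c(0.1, 1, 0.5, 0.05), c(0.6, 0.4, 0.3, 0.3))
  sol <- kmedoids(x, 2L, n_restarts = 3L, seed = 1L)
  sil <- medoid_silhouette(x, sol)
  d <- capdyn:::cor_distance_matrix(x)
  dm <- d[, sol$medoid_frame_indices]
  d1 <- apply(dm, 1L, min)
  d2 <- apply(dm, 1L, function(r) sort(r)[2L])
  expect_equal(sil$per_frame, ifelse(pmax(d1, d2) == 0, 0,
                                     (d2 - d1) / pmax(d1, d2)),
               tolerance = 1e-12)
  expect_equal(sil$mean, mean(sil$per_frame))
  # medoid frames themselves: d1 = 0 => silhouette 1 (unless degenerate)
  expect_true(all(sil$per_frame[sol$medoid_frame_indices] == 1))
})

test_that("state absence fraction counts subjects missing a state", {
  sol <- list(k = 2L, labels = c(1L, 2L, 1L, 1L, 2L, 2L, 1L, 1L))
  class(sol) <- "cluster_solution"
  idx <- rep(c("a", "b", "c", "d"), each = 2L)
  # subjects: a sees {1,2}, b sees {1}, c sees {2}, d sees {1}
  expect_equal(state_absence_fraction(sol, idx), 0.75)
  sol$labels <- rep(c(1L, 2L), 4L)
  expect_equal(state_absence_fraction(sol, idx), 0)
})

test_that("select_k returns the planted K and flags no-structure data", {
  cfg <- small_config(seed = 3L, subjects = 4L, frames = 150L)
  ds <- concatenate_cohort(lapply(generate_cohort(cfg)$time_series,
                                  normalize_subject))
  rep_k <- k_selection_report(ds, k_range = 2:6, n_restarts = 4L, seed = 9L)
  k <- select_k(rep_k)
  expect_identical(as.integer(k), 4L)
  expect_true(attr(k, "conclusive"))
  # structureless data: every criterion fails somewhere -> non-conclusive
  fake <- data.frame(k = 2:5, explained_variance = c(0.01, 0.02, 0.03, 0.04),
                     mean_medoid_silhouette = c(0.01, 0.02, 0.03, 0.04),
                     state_absence_fraction = 1,
                     max_centroid_correlation = 0.99)
  fake$variance_gain <- c(NA, diff(fake$explained_variance))
  expect_message(k2 <- select_k(fake), "non|compromise")
  expect_false(attr(k2, "conclusive"))
})

test_that("scan bookkeeping: frames per scan and the K ceiling", {
  expect_identical(frames_in_scan(10, 2.1), 286L)
  expect_identical(k_scan_ceiling(frames_in_scan(10, 2.1)), 17L)
})

test_that("higher k than planted raises the state-absence fraction", {
  cfg <- small_config(seed = 13L, subjects = 5L, frames = 80L)
  ds <- concatenate_cohort(lapply(generate_cohort(cfg)$time_series,
                                  normalize_subject))
  sol4 <- kmedoids(ds, 4L, n_restarts = 3L, seed = 1L)
  sol8 <- kmedoids(ds, 8L, n_restarts = 3L, seed = 1L)
  f4 <- state_absence_fraction(sol4, ds$frame_subject_index)
  f8 <- state_absence_fraction(sol8, ds$frame_subject_index)
  expect_gte(f8, f4)
})

test_that("state matching recovers shuffles and beats greedy assignment", {
  set.seed(6)
  a <- matrix(rnorm(4L * 20L), 4L, 20L)
  shuffle <- c(3L, 1L, 4L, 2L)
  m <- match_states(a, a[shuffle, ])
  expect_identical(order(shuffle), m$permutation)
  expect_equal(m$matched_correlations, rep(1, 4L), tolerance = 1e-12)
  # Hungarian equals brute force over all permutations, for random tables
  for (seed in 1:5) {
    set.seed(seed)
    cc <- matrix(runif(16L, -1, 1), 4L, 4L)
    perm_best <- -Inf
    for (p in asplit(gtools_permutations4(), 1L)) {
      perm_best <- max(perm_best, sum(cc[cbind(1:4, p)]))
    }
    got <- sum(cc[cbind(1:4, solve_assignment_test(cc))])
    expect_equal(got, perm_best, tolerance = 1e-12)
  }
})

test_that("split-half stability is near-perfect on duplicated data", {
  toy <- toy_two_state_series(n_rois = 10L, frames = 50L, noise_sd = 0.2,
                              seed = 4L)
  dup <- cbind(toy$ts$matrix, toy$ts$matrix)
  st <- split_half_stability(dup, 2L, n_splits = 3L, seed = 1L,
                             n_restarts = 2L)
  expect_true(all(st > 0.95))
})

test_that("structured data is more split-half stable than pure noise", {
  toy <- toy_two_state_series(n_rois = 10L, frames = 100L, noise_sd = 0.5,
                              seed = 5L)
  st_real <- split_half_stability(toy$ts$matrix, 2L, n_splits = 5L,
                                  seed = 2L, n_restarts = 2L)
  set.seed(77)
  noise <- matrix(rnorm(10L * 100L), 10L)
  st_null <- split_half_stability(noise, 2L, n_splits = 5L, seed = 2L,
                                  n_restarts = 2L)
  expect_gt(median(st_real), median(st_null))
})

test_that("network mapping splits signed components correctly", {
  parc <- default_parcellation(6L, c("VIS", "DMN"))
  cent <- c(1, 1, 1, 0, 0, 0)   # positive exactly on VIS
  m <- map_state_to_networks(cent, parc)
  expect_equal(m$positive[m$network == "VIS"], 1)
  expect_equal(m$positive[m$network == "DMN"], 0)
  expect_equal(m$negative, c(0, 0))
  # sign flip swaps the profiles
  m2 <- map_state_to_networks(-cent, parc)
  expect_equal(m2$negative, m$positive)
  expect_equal(m2$positive, m$negative)
  # planted patterns load most on their designated networks
  parc8 <- default_parcellation(40L)
  cent8 <- generate_state_patterns(4L, 40L, parc8, seed = 2L)
  design <- attr(cent8, "design")
  for (s in 1:4) {
    prof <- map_state_to_networks(cent8[s, ], parc8)
    top <- prof$network[order(-prof$positive)][seq_along(design[[s]])]
    expect_setequal(top, design[[s]])
  }
})
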