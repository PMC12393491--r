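# Small cohorts and toy datasets shared across test files.

small_config <- function(seed = 1L, n_rois = 40L, subjects = 3L,
                         frames = 120L, ...) {
  synthetic_config(n_rois = n_rois, n_subjects_per_group = subjects,
                   frames_per_subject = frames, seed = seed, ...)
}

# Two well-separated planted patterns emitted with tiny noise.
toy_two_state_series <- function(n_rois = 12L, frames = 60L, noise_sd = 1e-3,
                                 seed = 1L) {
  parc <- default_parcellation(n_rois, c("VIS", "DMN"))
  cent <- generate_state_patterns(2L, n_rois, parc, seed = seed)
  labels <- rep(rep(1:2, each = 5L), length.out = frames)
  list(centroids = cent, labels = labels,
       ts = emit_bold(labels, cent, 0, noise_sd, seed = seed + 1L))
}

# Brute-force k-medoids objective over all medoid subsets of size k.
brute_force_kmedoids_objective <- function(x, k) {
  d <- capdyn:::cor_distance_matrix(x)
  t_n <- ncol(x)
  best <- Inf
  for (idx in utils::combn(t_n, k, simplify = FALSE)) {
    obj <- sum(apply(d[, idx, drop = FALSE], 1L, min))
    if (obj < best) best <- obj
  }
  best
}

# All permutations of 1:4, one per row (enumeration oracle for matching).
gtools_permutations4 <- function() {
  out <- NULL
  for (a in 1:4) for (b in setdiff(1:4, a)) for (c in setdiff(1:4, c(a, b))) {
    out <- rbind(out, c(a, b, c, setdiff(1:4, c(a, b, c))))
  }
  out
}

# Maximize total correlation via the package's assignment solver.
solve_assignment_test <- function(cc) {
  capdyn:::solve_assignment(-cc)
}

# Empirical conditional transition matrix (includes self-transitions).
empirical_transition_matrix <- function(labels, k) {
  counts <- matrix(0, k, k)
  for (t in seq_len(length(labels) - 1L)) {
    counts[labels[t], labels[t + 1L]] <- counts[labels[t], labels[t + 1L]] + 1
  }
  counts / pmax(rowSums(counts), 1)
}
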