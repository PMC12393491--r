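#' Correlation distance between two activation maps
#'
#' `d = 1 - r` where `r` is the Pearson correlation across ROIs. Ranges over
#' `[0, 2]`: 0 for identical patterns, 2 for exact sign flips.
#'
#' @param frame_a,frame_b numeric vectors of equal length (at least 3).
#' @return Scalar distance in `[0, 2]`.
#' @export
correlation_distance <- function(frame_a, frame_b) {
  stopifnot(length(frame_a) == length(frame_b), length(frame_a) >= 3L)
  if (stats::sd(frame_a) == 0 || stats::sd(frame_b) == 0) {
    stop("correlation distance undefined for a constant activation map")
  }
  min(max(1 - stats::cor(frame_a, frame_b), 0), 2)
}

as_frame_matrix <- function(x) {
  if (inherits(x, "concatenated_dataset")) x$matrix else as.matrix(x)
}

# Unit-normalize frames (columns) so that crossprod(Z) is the frame-by-frame
# Pearson correlation matrix. Constant frames are rejected.
frame_unit_scores <- function(x) {
  x <- as_frame_matrix(x)
  z <- sweep(x, 2L, colMeans(x))
  nrm <- sqrt(colSums(z^2))
  if (any(nrm == 0)) {
    stop("constant frame(s) at column(s) ",
         paste(utils::head(which(nrm == 0), 5L), collapse = ", "),
         ": correlation distance undefined")
  }
  sweep(z, 2L, nrm, "/")
}

cor_distance_matrix <- function(x) {
  z <- frame_unit_scores(x)
  d <- 1 - crossprod(z)
  d[d < 0] <- 0
  d[d > 2] <- 2
  diag(d) <- 0
  d
}

# Distances from every frame to the frames indexed by `idx` (columns of the
# returned T x length(idx) matrix), computed without the full T x T matrix.
cor_distance_to <- function(z, idx) {
  d <- 1 - crossprod(z, z[, idx, drop = FALSE])
  d[d < 0] <- 0
  d[d > 2] <- 2
  d
}

# --- PAM core on a precomputed distance matrix ------------------------------

pam_build <- function(d, k) {
  t_n <- nrow(d)
  medoids <- which.min(colSums(d))
  dn <- d[, medoids]
  while (length(medoids) < k) {
    gains <- colSums(pmax(dn - d, 0))
    gains[medoids] <- -Inf
    m <- which.max(gains)
    medoids <- c(medoids, m)
    dn <- pmin(dn, d[, m])
  }
  medoids
}

nearest_two <- function(d, medoids) {
  dm <- d[, medoids, drop = FALSE]
  n1 <- max.col(-dm, ties.method = "first")
  d1 <- dm[cbind(seq_len(nrow(dm)), n1)]
  dm[cbind(seq_len(nrow(dm)), n1)] <- Inf
  d2 <- dm[cbind(seq_len(nrow(dm)), max.col(-dm, ties.method = "first"))]
  list(n1 = n1, d1 = d1, d2 = d2)
}

# FastPAM-style swap phase: evaluates all (medoid, candidate) swaps with
# vectorized O(k T^2) sweeps; objective is asserted to descend monotonically.
pam_swap <- function(d, medoids, max_iter = 100L) {
  k <- length(medoids)
  t_n <- nrow(d)
  obj <- function(meds) sum(nearest_two(d, meds)$d1)
  cur <- obj(medoids)
  for (iter in seq_len(max_iter)) {
    nt <- nearest_two(d, medoids)
    shared <- pmin(d - nt$d1, 0)        # T x T: candidate h in columns
    base <- colSums(shared)
    delta <- matrix(base, k, t_n, byrow = TRUE)
    for (i in seq_len(k)) {
      rows <- which(nt$n1 == i)
      if (length(rows) > 0L) {
        corr <- pmin(d[rows, , drop = FALSE], nt$d2[rows]) - nt$d1[rows] -
          shared[rows, , drop = FALSE]
        delta[i, ] <- delta[i, ] + colSums(corr)
      }
    }
    delta[, medoids] <- Inf
    best <- which(delta == min(delta), arr.ind = TRUE)[1L, , drop = TRUE]
    if (delta[best[1L], best[2L]] >= -1e-12) break
    medoids[best[1L]] <- best[2L]
    new <- obj(medoids)
    stopifnot(new <= cur + 1e-9)  # monotone descent
    cur <- new
  }
  medoids
}

finalize_solution <- function(x, z, medoids, restart_seed) {
  dm <- cor_distance_to(z, medoids)
  n1 <- max.col(-dm, ties.method = "first")
  # medoid frames belong to their own cluster by construction
  n1[medoids] <- seq_along(medoids)
  k <- length(medoids)
  cent <- t(vapply(seq_len(k), function(c) {
    rowMeans(x[, n1 == c, drop = FALSE])
  }, numeric(nrow(x))))
  structure(list(
    k = k,
    medoid_frame_indices = as.integer(medoids),
    labels = as.integer(n1),
    mean_centroids = cent,
    total_within_distance = sum(dm[cbind(seq_along(n1), n1)]),
    restart_seed = restart_seed), class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("<cluster_solution> k =", x$k, "- total within-cluster distance",
      signif(x$total_within_distance, 6), "\n")
  cat("  cluster sizes:", paste(tabulate(x$labels, x$k), collapse = ", "), "\n")
  invisible(x)
}

#' k-medoids clustering of fMRI frames with correlation distance
#'
#' Partitions the frames (columns) of a concatenated dataset into `k`
#' clusters of co-activation patterns. Two exact-objective algorithms are
#' provided:
#' \describe{
#'   \item{`"pam"`}{classic PAM on the precomputed frame-by-frame correlation
#'     distance matrix: greedy BUILD initialization followed by a swap phase
#'     whose objective descends monotonically. Restart 1 starts from BUILD;
#'     further restarts start from random medoid sets, each refined by the
#'     swap phase.}
#'   \item{`"alternate"`}{for datasets too large for an `O(T^2)` matrix:
#'     PAM on a random frame subsample initializes alternating assignment /
#'     exact medoid-update sweeps over the full data. The medoid update
#'     exploits the identity `sum_o d(o, j) = |C| - z_j . sum_{o in C} z_o`
#'     for unit-normalized frames, so it is exact at `O(N T)` cost.}
#' }
#' The restart minimizing total within-cluster correlation distance is
#' returned (`final = "min"`); `final = "max"` selects the maximum instead.
#'
#' @param dataset a [concatenate_cohort()] result or an `N x T` matrix.
#' @param k number of clusters, `2 <= k < T`.
#' @param n_restarts number of restarts.
#' @param seed integer seed driving all restarts.
#' @param method `"auto"` (PAM when `T <= max_exact`, else alternate),
#'   `"pam"`, or `"alternate"`.
#' @param max_exact largest `T` for which the full distance matrix is built.
#' @param sample_size subsample size for the alternate method's PAM
#'   initialization.
#' @param final `"min"` or `"max"`: which restart objective is kept.
#' @return A `cluster_solution`: `k`, `medoid_frame_indices`, `labels`
#'   (nearest-medoid assignment), `mean_centroids` (`K x N` cluster means),
#'   `total_within_distance`, `restart_seed`.
#' @export
kmedoids <- function(dataset, k, n_restarts = 10L, seed = 1L,
                     method = c("auto", "pam", "alternate"),
                     max_exact = 4000L, sample_size = 2000L,
                     final = c("min", "max")) {
  method <- match.arg(method)
  final <- match.arg(final)
  x <- as_frame_matrix(dataset)
  t_n <- ncol(x)
  stopifnot(k >= 2L, t_n > k, n_restarts >= 1L)
  z <- frame_unit_scores(x)
  if (method == "auto") method <- if (t_n <= max_exact) "pam" else "alternate"
  solutions <- vector("list", n_restarts)
  if (method == "pam") {
    d <- cor_distance_matrix(x)
    for (r in seq_len(n_restarts)) {
      rs <- as.integer(seed) + r - 1L
      init <- if (r == 1L) {
        pam_build(d, k)
      } else {
        set.seed(rs)
        sample.int(t_n, k)
      }
      med <- pam_swap(d, init)
      solutions[[r]] <- finalize_solution(x, z, med, rs)
    }
  } else {
    for (r in seq_len(n_restarts)) {
      rs <- as.integer(seed) + r - 1L
      set.seed(rs)
      sub <- sort(sample.int(t_n, min(sample_size, t_n)))
      dsub <- cor_distance_matrix(x[, sub, drop = FALSE])
      med <- sub[pam_swap(dsub, pam_build(dsub, k))]
      med <- alternate_kmedoids(z, med)
      solutions[[r]] <- finalize_solution(x, z, med, rs)
    }
  }
  objs <- vapply(solutions, `[[`, numeric(1L), "total_within_distance")
  solutions[[if (final == "min") which.min(objs) else which.max(objs)]]
}

# Alternating (Voronoi) k-medoids refinement over the full dataset; exact
# medoid updates via the linearity of correlation-distance sums.
alternate_kmedoids <- function(z, medoids, max_iter = 100L) {
  t_n <- ncol(z)
  k <- length(medoids)
  for (iter in seq_len(max_iter)) {
    dm <- cor_distance_to(z, medoids)
    n1 <- max.col(-dm, ties.method = "first")
    n1[medoids] <- seq_len(k)
    empty <- setdiff(seq_len(k), unique(n1))
    for (e in empty) {
      # re-seed an emptied medoid at the frame farthest from its nearest medoid
      far <- which.max(dm[cbind(seq_len(t_n), n1)])
      message("alternate_kmedoids: empty cluster ", e,
              " re-seeded at frame ", far)
      medoids[e] <- far
      n1[far] <- e
    }
    new_med <- medoids
    for (c in seq_len(k)) {
      members <- which(n1 == c)
      s_c <- rowSums(z[, members, drop = FALSE])
      # argmin_j sum_{o in C} d(o, j) = argmax_j z_j . s_C
      new_med[c] <- members[which.max(crossprod(z[, members, drop = FALSE], s_c))]
    }
    if (all(new_med == medoids)) break
    medoids <- new_med
  }
  medoids
}

# Exact grand medoid under squared correlation distance, via the N x N Gram
# trick: sum_o d(o,j)^2 = T - 2 z_j.s + z_j' (Z Z') z_j.
grand_medoid_sq <- function(z) {
  t_n <- ncol(z)
  s <- rowSums(z)
  g <- tcrossprod(z)
  q <- colSums(z * (g %*% z))
  which.min(t_n - 2 * as.numeric(crossprod(z, s)) + q)
}

#' Explained variance of a clustering solution
#'
#' `EV = 1 - sum_o d(o, medoid(o))^2 / sum_o d(o, grand medoid)^2`, with `d`
#' the correlation distance and the grand medoid the frame minimizing the
#' total squared distance to all frames. `EV = 0` for `k = 1` by definition
#' and `EV = 1` when every frame is its own medoid.
#'
#' @param dataset the clustered dataset.
#' @param solution a `cluster_solution` from [kmedoids()].
#' @return Scalar in `[0, 1]`.
#' @export
explained_variance <- function(dataset, solution) {
  z <- frame_unit_scores(dataset)
  dm <- cor_distance_to(z, solution$medoid_frame_indices)
  num <- sum(dm[cbind(seq_along(solution$labels), solution$labels)]^2)
  g <- grand_medoid_sq(z)
  den <- sum(cor_distance_to(z, g)^2)
  if (den == 0) return(1)
  max(0, min(1, 1 - num / den))
}

#' Variance gain at k
#'
#' `gain(k) = EV(k) - EV(k - 1)` read from a [k_selection_report()]. `NA`
#' when `k - 1` is not in the scanned range.
#'
#' @param report a `k_selection_report` data.frame.
#' @param k cluster count.
#' @return Scalar gain, or `NA_real_` if undefined.
#' @export
variance_gain <- function(report, k) {
  i <- match(k, report$k)
  j <- match(k - 1L, report$k)
  if (is.na(i) || is.na(j)) return(NA_real_)
  report$explained_variance[i] - report$explained_variance[j]
}

#' Medoid silhouette of a clustering solution
#'
#' Per frame, `s = (d2 - d1) / max(d1, d2)` with `d1` and `d2` the
#' correlation distances to the nearest and second-nearest medoids. The
#' degenerate case `d1 = d2 = 0` is defined as 0.
#'
#' @inheritParams explained_variance
#' @return List with `per_frame` (length-`T` vector) and `mean`.
#' @export
medoid_silhouette <- function(dataset, solution) {
  stopifnot(solution$k >= 2L)
  z <- frame_unit_scores(dataset)
  dm <- cor_distance_to(z, solution$medoid_frame_indices)
  n1 <- max.col(-dm, ties.method = "first")
  d1 <- dm[cbind(seq_len(nrow(dm)), n1)]
  dm[cbind(seq_len(nrow(dm)), n1)] <- Inf
  d2 <- dm[cbind(seq_len(nrow(dm)), max.col(-dm, ties.method = "first"))]
  denom <- pmax(d1, d2)
  s <- ifelse(denom == 0, 0, (d2 - d1) / denom)
  list(per_frame = s, mean = mean(s))
}

#' Fraction of subjects with at least one absent state
#'
#' @param solution a `cluster_solution`.
#' @param frame_subject_index subject id per frame (as in
#'   [concatenate_cohort()]).
#' @return Scalar in `[0, 1]`.
#' @export
state_absence_fraction <- function(solution, frame_subject_index) {
  stopifnot(length(frame_subject_index) == length(solution$labels))
  per_sub <- split(solution$labels, frame_subject_index)
  mean(vapply(per_sub, function(l) {
    length(unique(l)) < solution$k
  }, logical(1L)))
}

#' K-selection metric scan
#'
#' Runs [kmedoids()] for each `k` in `k_range` and tabulates the selection
#' criteria: explained variance, variance gain, mean medoid silhouette,
#' state-absence fraction, and the maximum off-diagonal Pearson correlation
#' between cluster-mean centroids.
#'
#' @inheritParams kmedoids
#' @param k_range contiguous integer vector of cluster counts.
#' @param frame_subject_index subject id per frame; defaults to the dataset's
#'   own map when a `concatenated_dataset` is given.
#' @param ... passed to [kmedoids()].
#' @return A data.frame of class `k_selection_report` with one row per `k`,
#'   plus attribute `solutions` (the per-k `cluster_solution`s).
#' @export
k_selection_report <- function(dataset, k_range = 2:17, n_restarts = 10L,
                               seed = 1L, frame_subject_index = NULL, ...) {
  stopifnot(all(diff(k_range) == 1L))
  if (is.null(frame_subject_index) && inherits(dataset, "concatenated_dataset")) {
    frame_subject_index <- dataset$frame_subject_index
  }
  sols <- lapply(k_range, function(k) {
    kmedoids(dataset, k, n_restarts = n_restarts, seed = seed + 100L * k, ...)
  })
  rep_df <- data.frame(
    k = as.integer(k_range),
    explained_variance = vapply(sols, function(s) {
      explained_variance(dataset, s)
    }, numeric(1L)),
    mean_medoid_silhouette = vapply(sols, function(s) {
      medoid_silhouette(dataset, s)$mean
    }, numeric(1L)),
    state_absence_fraction = if (is.null(frame_subject_index)) NA_real_ else
      vapply(sols, state_absence_fraction, numeric(1L),
             frame_subject_index = frame_subject_index),
    max_centroid_correlation = vapply(sols, function(s) {
      cc <- stats::cor(t(s$mean_centroids))
      max(cc[upper.tri(cc)])
    }, numeric(1L)))
  rep_df$variance_gain <- c(NA_real_, diff(rep_df$explained_variance))
  attr(rep_df, "solutions") <- stats::setNames(sols, paste0("k", k_range))
  class(rep_df) <- c("k_selection_report", "data.frame")
  rep_df
}

#' Select the number of brain states from a metric scan
#'
#' Returns the smallest `k` in the scanned range such that (i) the variance
#' gain of moving to `k + 1` falls below `gain_threshold`, (ii) the mean
#' medoid silhouette at `k` is locally maximal or within `silhouette_tol` of
#' its neighbor at `k + 1` (plateau), (iii) the state-absence fraction is at
#' most `absence_threshold`, and (iv) the maximum centroid correlation is at
#' most `correlation_threshold`. If no `k` satisfies all four, the `k`
#' satisfying the most criteria (ties to smallest) is returned flagged
#' non-conclusive.
#'
#' @param report a [k_selection_report()].
#' @param gain_threshold variance-gain cutoff (default 0.01).
#' @param silhouette_tol plateau tolerance for the silhouette criterion.
#' @param absence_threshold maximum tolerated state-absence fraction.
#' @param correlation_threshold maximum tolerated centroid correlation.
#' @return Integer `k` with attributes `conclusive` (logical) and `criteria`
#'   (logical matrix of per-k criterion outcomes).
#' @export
select_k <- function(report, gain_threshold = 0.01, silhouette_tol = 0.02,
                     absence_threshold = 0.25, correlation_threshold = 0.5) {
  ks <- report$k
  n <- length(ks)
  next_gain <- c(report$variance_gain[-1L], NA_real_)
  sil <- report$mean_medoid_silhouette
  crit <- cbind(
    gain_tapers = !is.na(next_gain) & next_gain < gain_threshold,
    silhouette_plateau = c(sil[-n] >= sil[-1L] - silhouette_tol, FALSE),
    states_represented = is.na(report$state_absence_fraction) |
      report$state_absence_fraction <= absence_threshold,
    centroids_distinct = report$max_centroid_correlation <= correlation_threshold)
  rownames(crit) <- paste0("k", ks)
  ok <- which(rowSums(crit) == ncol(crit))
  if (length(ok) > 0L) {
    k <- ks[ok[1L]]
    conclusive <- TRUE
  } else {
    score <- rowSums(crit)
    k <- ks[which.max(score)]
    conclusive <- FALSE
    message("select_k: no k satisfies all criteria; best compromise k = ", k,
            " (", max(score), "/", ncol(crit), " criteria)")
  }
  structure(as.integer(k), conclusive = conclusive, criteria = crit)
}

#' Theoretical upper bound of the K scan for one scan's length
#'
#' The smallest `k` whose `k^2` possible ordered state transitions exceed the
#' number of frames in a scan, i.e. the largest `k` at which every transition
#' could in principle be observed at least once within the scan.
#'
#' @param n_frames frames per scan.
#' @return Integer `k`.
#' @export
k_scan_ceiling <- function(n_frames) {
  as.integer(floor(sqrt(n_frames))) + 1L
}

#' Frames in a scan of a given duration
#'
#' @param minutes scan duration in minutes.
#' @param tr_seconds repetition time in seconds.
#' @return Integer frame count (`round(minutes * 60 / tr_seconds)`).
#' @export
frames_in_scan <- function(minutes, tr_seconds) {
  as.integer(round(minutes * 60 / tr_seconds))
}

# Hungarian algorithm (shortest augmenting path with potentials); minimizes
# total cost over permutations. Hand-rolled: no LSAP solver is available.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)          # p[j+1]: row assigned to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0L:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  perm <- integer(n)            # perm[row] = assigned column
  for (j in seq_len(n)) perm[p[j + 1L]] <- j
  perm
}

#' Match two sets of state centroids
#'
#' Finds the bijection between the states of two solutions maximizing the
#' total Pearson correlation of matched centroids (assignment problem solved
#' by the Hungarian method, so the match is deterministic and
#' order-independent).
#'
#' @param centroids_a,centroids_b `K x N` centroid matrices with equal
#'   dimensions.
#' @return List of class `state_match`: `permutation` (state `i` of `a`
#'   matches state `permutation[i]` of `b`), `matched_correlations`,
#'   `total_correlation`, `correlation_matrix`.
#' @export
match_states <- function(centroids_a, centroids_b) {
  stopifnot(nrow(centroids_a) == nrow(centroids_b),
            ncol(centroids_a) == ncol(centroids_b))
  cc <- stats::cor(t(centroids_a), t(centroids_b))
  perm <- solve_assignment(-cc)
  structure(list(
    permutation = perm,
    matched_correlations = cc[cbind(seq_len(nrow(cc)), perm)],
    total_correlation = sum(cc[cbind(seq_len(nrow(cc)), perm)]),
    correlation_matrix = cc), class = "state_match")
}

#' Split-half stability of the state centroids
#'
#' Repeatedly permutes the frames, splits them into two equal halves (an odd
#' frame is dropped, with a message), clusters each half at the same `k`, and
#' matches the two centroid sets with [match_states()]. The distribution of
#' matched correlations measures the reproducibility of the states.
#'
#' @inheritParams kmedoids
#' @param n_splits number of random splits.
#' @param ... passed to [kmedoids()].
#' @return `n_splits x k` matrix of matched correlations.
#' @export
split_half_stability <- function(dataset, k, n_splits = 50L, seed = 1L,
                                 n_restarts = 5L, ...) {
  x <- as_frame_matrix(dataset)
  t_n <- ncol(x)
  if (t_n %% 2L == 1L) {
    message("split_half_stability: odd frame count, dropping the last frame")
    t_n <- t_n - 1L
  }
  half <- t_n %/% 2L
  out <- matrix(NA_real_, n_splits, k)
  for (s in seq_len(n_splits)) {
    set.seed(as.integer(seed) + s - 1L)
    perm <- sample.int(t_n)
    sol_a <- kmedoids(x[, perm[seq_len(half)], drop = FALSE], k,
                      n_restarts = n_restarts, seed = seed + 7919L * s, ...)
    sol_b <- kmedoids(x[, perm[half + seq_len(half)], drop = FALSE], k,
                      n_restarts = n_restarts, seed = seed + 7919L * s + 1L, ...)
    m <- match_states(sol_a$mean_centroids, sol_b$mean_centroids)
    out[s, ] <- m$matched_correlations
  }
  out
}

#' Map a state centroid onto resting-state networks
#'
#' Splits a centroid into its above-baseline (`x+ = max(x, 0)`) and
#' below-baseline (`|x-| = |min(x, 0)|`) components and computes the cosine
#' similarity of each component with every network's indicator vector. Both
#' similarities lie in `[0, 1]`; an all-zero component maps to 0.
#'
#' @param centroid numeric vector over ROIs (z-units).
#' @param parcellation a [parcellation_table()] matching the centroid.
#' @return data.frame with columns `network`, `positive`, `negative`.
#' @export
map_state_to_networks <- function(centroid, parcellation) {
  stopifnot(length(centroid) == nrow(parcellation))
  pos <- pmax(centroid, 0)
  neg <- -pmin(centroid, 0)
  nets <- unique(parcellation$network)
  cos_part <- function(x, ind) {
    nx <- sqrt(sum(x^2))
    if (nx == 0) return(0)
    sum(x * ind) / (nx * sqrt(sum(ind^2)))
  }
  data.frame(
    network = nets,
    positive = vapply(nets, function(g) {
      cos_part(pos, as.numeric(parcellation$network == g))
    }, numeric(1L)),
    negative = vapply(nets, function(g) {
      cos_part(neg, as.numeric(parcellation$network == g))
    }, numeric(1L)),
    row.names = NULL)
}
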