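#' Phase-randomized surrogate of a regional time series
#'
#' Per ROI: Fourier-transform the series, multiply every positive-frequency
#' coefficient by `exp(i*theta)` with `theta` uniform on `[0, 2*pi)`, mirror
#' the conjugate onto negative frequencies, keep the DC term (and, for even
#' length, the Nyquist term) untouched, and invert. The surrogate has exactly
#' the original per-ROI amplitude spectrum — hence the original
#' autocorrelation function and variance (Parseval) and mean — but scrambled
#' temporal structure.
#'
#' With `mode = "independent"` (default) each ROI draws its own phases,
#' destroying cross-ROI zero-lag co-activation structure; with
#' `mode = "locked"` all ROIs share one phase draw, preserving zero-lag
#' cross-correlations.
#'
#' @param ts a [regional_time_series()] with at least 4 frames.
#' @param seed integer seed.
#' @param mode `"independent"` or `"locked"`.
#' @return A `regional_time_series` whose `subject_id` is suffixed
#'   `"_surr<seed>"`; attribute `provenance` records source and seed.
#' @export
phase_randomize <- function(ts, seed = 1L, mode = c("independent", "locked")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ts, "regional_time_series"))
  x <- ts$matrix
  if (any(!is.finite(x))) stop("non-finite input to phase_randomize")
  t_n <- ncol(x)
  if (t_n < 4L) stop("phase randomization needs at least 4 frames")
  n_pos <- (t_n - 1L) %/% 2L        # strictly positive, non-Nyquist freqs
  set.seed(as.integer(seed))
  n_rois <- nrow(x)
  surr <- x
  theta_locked <- stats::runif(n_pos, 0, 2 * pi)
  for (r in seq_len(n_rois)) {
    f <- stats::fft(x[r, ])
    theta <- if (mode == "locked") theta_locked else stats::runif(n_pos, 0, 2 * pi)
    rot <- exp(1i * theta)
    if (n_pos > 0L) {
      f[2L:(n_pos + 1L)] <- f[2L:(n_pos + 1L)] * rot
      f[t_n:(t_n - n_pos + 1L)] <- Conj(f[2L:(n_pos + 1L)])
    }
    # DC (f[1]) and, for even T, the Nyquist bin f[T/2 + 1] stay untouched
    surr[r, ] <- Re(stats::fft(f, inverse = TRUE)) / t_n
  }
  out <- regional_time_series(paste0(ts$subject_id, "_surr", seed), surr,
                              ts$tr_seconds, roi_labels = ts$roi_labels)
  attr(out, "provenance") <- list(source_subject = ts$subject_id,
                                  seed = as.integer(seed), mode = mode)
  out
}

#' Phase-randomized surrogate cohort
#'
#' Applies [phase_randomize()] to every subject (before concatenation, so
#' subject boundaries match the real pipeline) with per-subject seeds derived
#' deterministically from `seed`.
#'
#' @param ts_list list of [regional_time_series()].
#' @param seed integer seed.
#' @param mode passed to [phase_randomize()].
#' @return List of surrogate `regional_time_series`.
#' @export
phase_randomize_cohort <- function(ts_list, seed = 1L,
                                   mode = "independent") {
  lapply(seq_along(ts_list), function(i) {
    phase_randomize(ts_list[[i]], seed = as.integer(seed) + 131L * i,
                    mode = mode)
  })
}

per_cluster_within_variance <- function(dataset, solution) {
  z <- frame_unit_scores(dataset)
  dm <- cor_distance_to(z, solution$medoid_frame_indices)
  d_own <- dm[cbind(seq_along(solution$labels), solution$labels)]
  vapply(seq_len(solution$k), function(c) {
    mean(d_own[solution$labels == c]^2)
  }, numeric(1L))
}

#' Real-versus-null cluster quality comparison
#'
#' Clusters the real cohort, then generates `n_surrogates` phase-randomized
#' cohorts and clusters each with the identical pipeline. Reports the
#' difference in mean medoid silhouette (real minus null mean) and
#' per-cluster within-cluster variance (mean squared correlation distance to
#' the medoid) differences, with empirical permutation-style p-values
#' `p = (1 + #surrogates >= real) / (1 + n_surrogates)` for the silhouette
#' (larger-is-better one-sided).
#'
#' @param ts_list list of normalized [regional_time_series()] (the real
#'   cohort).
#' @param n_surrogates number of surrogate cohorts, at least 2.
#' @param k number of clusters.
#' @param seed integer seed.
#' @param mode surrogate mode, see [phase_randomize()].
#' @param ... passed to [kmedoids()].
#' @return List: `delta_silhouette`, `p_silhouette`, `real_silhouette`,
#'   `null_silhouettes`, `delta_within_variance` (per cluster, real minus
#'   null mean), `n_used` (surrogates successfully clustered).
#' @export
compare_cluster_quality <- function(ts_list, n_surrogates, k, seed = 1L,
                                    mode = "independent", ...) {
  if (n_surrogates < 2L) {
    stop("n_surrogates must be at least 2, got ", n_surrogates)
  }
  real_ds <- concatenate_cohort(ts_list)
  real_sol <- kmedoids(real_ds, k, seed = seed, ...)
  real_sil <- medoid_silhouette(real_ds, real_sol)$mean
  real_wv <- per_cluster_within_variance(real_ds, real_sol)
  null_sil <- numeric(0)
  null_wv <- NULL
  for (b in seq_len(n_surrogates)) {
    sil_b <- tryCatch({
      surr <- phase_randomize_cohort(ts_list, seed = seed + 10000L * b,
                                     mode = mode)
      ds_b <- concatenate_cohort(surr)
      sol_b <- kmedoids(ds_b, k, seed = seed + b, ...)
      wv_b <- sort(per_cluster_within_variance(ds_b, sol_b))
      null_wv <- rbind(null_wv, wv_b)
      medoid_silhouette(ds_b, sol_b)$mean
    }, error = function(e) {
      message("compare_cluster_quality: surrogate ", b, " skipped (",
              conditionMessage(e), ")")
      NA_real_
    })
    null_sil <- c(null_sil, sil_b)
  }
  used <- sum(!is.na(null_sil))
  ns <- null_sil[!is.na(null_sil)]
  list(delta_silhouette = real_sil - mean(ns),
       p_silhouette = (1 + sum(ns >= real_sil)) / (1 + used),
       real_silhouette = real_sil,
       null_silhouettes = ns,
       real_within_variance = real_wv,
       delta_within_variance = sort(real_wv) - colMeans(null_wv, na.rm = TRUE),
       n_used = used)
}
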