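#' Default ROI-to-network partition
#'
#' Splits `n_rois` ROIs over the given networks as evenly as possible, in
#' label order. Used as the default parcellation for synthetic cohorts.
#'
#' @param n_rois integer ROI count.
#' @param networks character vector of network labels.
#' @return A [parcellation_table()].
#' @export
default_parcellation <- function(n_rois, networks = rsn_networks()) {
  m <- length(networks)
  sizes <- rep(n_rois %/% m, m)
  extra <- n_rois %% m
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  parcellation_table(paste0("ROI", seq_len(n_rois)), rep(networks, sizes))
}

#' Configuration for a synthetic cohort
#'
#' Bundles every parameter of the synthetic-data generator. The defaults
#' mirror the study conditions the pipeline is designed for: two groups of 38
#' subjects, 286 frames per subject at TR 2.1 s, 85 ROIs over 8 resting-state
#' networks, K = 4 planted states, AR(1) noise with coefficient 0.45.
#'
#' The two group transition matrices are row-stochastic and include
#' self-transitions; the planted group contrast gives the control group a
#' preference for switching between states 1 and 4 and the patient group a
#' preference for the 2-3 loop with a shorter dwell in state 3.
#'
#' @param k_states number of planted states.
#' @param n_rois number of ROIs.
#' @param n_subjects_per_group subjects per group.
#' @param frames_per_subject frames per scan.
#' @param tr_seconds repetition time (seconds).
#' @param ar_coefficient AR(1) noise coefficient, in `[0, 1)`.
#' @param noise_sd innovation standard deviation of the AR(1) noise
#'   (z-units), nonnegative.
#' @param group_transition_matrices named list with elements `HC` and `MDD`,
#'   each a row-stochastic `K x K` matrix (rows sum to 1 within `1e-12`).
#' @param clinical_coupling named numeric vector: slope of each clinical
#'   score's mean on the planted fractional occupancy (percent) of
#'   `coupled_state`.
#' @param clinical_noise_sd standard deviation of the score noise.
#' @param coupled_state index of the state whose fractional occupancy drives
#'   the clinical scores.
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the config.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(k_states = 4L,
                             n_rois = 85L,
                             n_subjects_per_group = 38L,
                             frames_per_subject = 286L,
                             tr_seconds = 2.1,
                             ar_coefficient = 0.45,
                             noise_sd = 0.8,
                             group_transition_matrices = default_group_transitions(k_states),
                             clinical_coupling = default_clinical_coupling(),
                             clinical_noise_sd = 2,
                             coupled_state = 3L,
                             seed = 1L) {
  stopifnot(k_states >= 2L, n_rois >= 2L * k_states,
            frames_per_subject >= k_states,
            tr_seconds > 0, noise_sd >= 0,
            ar_coefficient >= 0, ar_coefficient < 1)
  stopifnot(is.list(group_transition_matrices),
            all(c("HC", "MDD") %in% names(group_transition_matrices)))
  for (g in c("HC", "MDD")) {
    P <- group_transition_matrices[[g]]
    check_stochastic(P, k_states, paste0("group ", g))
  }
  structure(list(
    k_states = as.integer(k_states), n_rois = as.integer(n_rois),
    n_subjects_per_group = as.integer(n_subjects_per_group),
    frames_per_subject = as.integer(frames_per_subject),
    tr_seconds = tr_seconds, ar_coefficient = ar_coefficient,
    noise_sd = noise_sd,
    group_transition_matrices = group_transition_matrices,
    clinical_coupling = clinical_coupling,
    clinical_noise_sd = clinical_noise_sd,
    coupled_state = as.integer(coupled_state),
    seed = as.integer(seed)), class = "synthetic_config")
}

check_stochastic <- function(P, k = nrow(P), what = "transition matrix") {
  if (!is.matrix(P) || nrow(P) != k || ncol(P) != k) {
    stop(what, " must be ", k, " x ", k)
  }
  if (any(P < 0)) stop(what, " has negative entries")
  bad <- which(abs(rowSums(P) - 1) > 1e-12)
  if (length(bad) > 0L) {
    stop(what, " row ", bad[1L], " sums to ", rowSums(P)[bad[1L]],
         ", not 1 (tolerance 1e-12)")
  }
  invisible(P)
}

#' Default planted group transition matrices
#'
#' For `k_states = 4`, the control (HC) matrix favors 1-4 switching and the
#' patient (MDD) matrix favors the 2-3 loop with a shallower self-transition
#' for state 3 (shorter dwell, higher turnover). For other K a common
#' baseline with a single contrasted off-diagonal pair is built.
#'
#' @param k_states number of states.
#' @return Named list with `HC` and `MDD` row-stochastic matrices.
#' @export
default_group_transitions <- function(k_states = 4L) {
  if (k_states == 4L) {
    hc <- matrix(c(
      0.70, 0.07, 0.07, 0.16,
      0.10, 0.70, 0.10, 0.10,
      0.10, 0.10, 0.70, 0.10,
      0.16, 0.07, 0.07, 0.70), 4, 4, byrow = TRUE)
    mdd <- matrix(c(
      0.70, 0.10, 0.12, 0.08,
      0.07, 0.70, 0.16, 0.07,
      0.09, 0.22, 0.60, 0.09,
      0.08, 0.12, 0.10, 0.70), 4, 4, byrow = TRUE)
    return(list(HC = hc, MDD = mdd))
  }
  base <- matrix(0.3 / (k_states - 1), k_states, k_states)
  diag(base) <- 0.7
  hc <- mdd <- base
  # contrast the (1,2) pair: HC switches 1->2 more, MDD less
  shift <- 0.15 / (k_states - 1)
  hc[1L, 2L] <- hc[1L, 2L] + shift
  hc[1L, -c(1L, 2L)] <- hc[1L, -c(1L, 2L)] - shift / (k_states - 2)
  mdd[1L, 2L] <- mdd[1L, 2L] - shift
  mdd[1L, -c(1L, 2L)] <- mdd[1L, -c(1L, 2L)] + shift / (k_states - 2)
  list(HC = hc, MDD = mdd)
}

#' Default clinical coupling slopes
#'
#' Slopes (score units per percent fractional occupancy of the coupled state)
#' used to generate clinical scores. Depression and anhedonia scores are
#' coupled most strongly, mirroring the designed role of state 3 as the
#' symptom-relevant state; rumination scores weakly.
#'
#' @return Named numeric vector over the seven score columns.
#' @export
default_clinical_coupling <- function() {
  c(QIDS = 0.5, MASQ_AD = 0.6, MASQ_AA = 0.2, MASQ_GD = 0.3,
    RRS_DEP = 0.25, RRS_BRO = 0.2, RRS_REF = 0.15)
}

#' Generate planted co-activation state patterns
#'
#' Builds `k_states` centroid patterns over `n_rois` ROIs. Networks are dealt
#' round-robin to states; each state's designated networks are set positive
#' and all others negative, ROI-level jitter is added, and each pattern is
#' z-scored across ROIs (population convention). The construction guarantees
#' spatially distinct states: any pair of patterns shares no positive
#' network, so all pairwise Pearson correlations are well below 0.3
#' (verified, with an explicit failure otherwise).
#'
#' @param k_states number of states.
#' @param n_rois number of ROIs; must be at least `2 * k_states`.
#' @param network_partition a [parcellation_table()] covering all ROIs.
#' @param seed integer seed.
#' @param jitter_sd ROI-level jitter standard deviation before z-scoring.
#' @return `k_states x n_rois` matrix; rows have mean 0 and population sd 1.
#'   Attribute `design` records each state's positive networks.
#' @export
generate_state_patterns <- function(k_states, n_rois, network_partition,
                                    seed = 1L, jitter_sd = 0.2) {
  if (n_rois < 2L * k_states) {
    stop("infeasible separation: need n_rois >= 2*k_states (",
         n_rois, " < ", 2L * k_states, ")")
  }
  stopifnot(nrow(network_partition) == n_rois)
  nets <- unique(network_partition$network)
  if (length(nets) < k_states) {
    stop("infeasible separation: ", length(nets), " networks for ",
         k_states, " states; each state needs a distinct positive network")
  }
  net_of_state <- split(nets, rep(seq_len(k_states), length.out = length(nets)))
  set.seed(as.integer(seed))
  cent <- matrix(0, k_states, n_rois)
  for (s in seq_len(k_states)) {
    pos <- network_partition$network %in% net_of_state[[s]]
    # balance positive and negative mass so the raw pattern is near zero-mean
    cent[s, pos] <- sum(!pos) / n_rois
    cent[s, !pos] <- -sum(pos) / n_rois
    cent[s, ] <- cent[s, ] + stats::rnorm(n_rois, 0, jitter_sd)
    cent[s, ] <- cent[s, ] - mean(cent[s, ])
    cent[s, ] <- cent[s, ] / sqrt(mean(cent[s, ]^2))
  }
  if (k_states > 1L) {
    cc <- stats::cor(t(cent))
    off <- cc[upper.tri(cc)]
    if (any(off >= 0.3)) {
      stop("infeasible separation: planted centroid correlation ",
           signif(max(off), 3), " >= 0.3")
    }
  }
  colnames(cent) <- network_partition$roi_label
  attr(cent, "design") <- net_of_state
  cent
}

stationary_distribution <- function(P) {
  k <- nrow(P)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

#' Simulate a Markov state sequence
#'
#' Draws a first-order Markov chain of length `n_frames` from a
#' row-stochastic transition matrix. The initial state is drawn from the
#' stationary distribution, so the sequence is stationary from frame 1 (no
#' burn-in bias).
#'
#' @param transition_matrix row-stochastic `K x K` matrix (rows sum to 1
#'   within `1e-12`).
#' @param n_frames sequence length, at least 1.
#' @param seed integer seed.
#' @return Integer vector of labels in `1..K`.
#' @export
simulate_state_sequence <- function(transition_matrix, n_frames, seed = 1L) {
  check_stochastic(transition_matrix)
  stopifnot(n_frames >= 1L)
  k <- nrow(transition_matrix)
  set.seed(as.integer(seed))
  cum <- t(apply(transition_matrix, 1L, cumsum))
  labels <- integer(n_frames)
  labels[1L] <- sample.int(k, 1L, prob = stationary_distribution(transition_matrix))
  if (n_frames > 1L) {
    u <- stats::runif(n_frames - 1L)
    for (t in 2L:n_frames) {
      labels[t] <- findInterval(u[t - 1L], cum[labels[t - 1L], ]) + 1L
    }
  }
  labels
}

#' Emit BOLD from a state sequence
#'
#' Frame `t` equals the centroid of the active state plus per-ROI AR(1)
#' noise: `e_t = phi * e_{t-1} + eta_t`, `eta ~ N(0, noise_sd^2)`, with the
#' first noise sample drawn from the stationary AR(1) marginal
#' `N(0, noise_sd^2 / (1 - phi^2))`.
#'
#' @param labels integer state labels (one per frame).
#' @param centroids `K x N` matrix of state patterns.
#' @param ar_coefficient AR(1) coefficient `phi`, `|phi| < 1`.
#' @param noise_sd innovation standard deviation.
#' @param seed integer seed.
#' @param tr_seconds repetition time for the resulting series.
#' @param subject_id identifier for the resulting series.
#' @return A [regional_time_series()], `N x length(labels)`.
#' @export
emit_bold <- function(labels, centroids, ar_coefficient, noise_sd, seed = 1L,
                      tr_seconds = 2.1, subject_id = "synthetic") {
  if (abs(ar_coefficient) >= 1) {
    stop("AR(1) coefficient must satisfy |phi| < 1, got ", ar_coefficient)
  }
  stopifnot(noise_sd >= 0, all(labels >= 1L), all(labels <= nrow(centroids)))
  n <- ncol(centroids)
  t_frames <- length(labels)
  x <- t(centroids)[, labels, drop = FALSE]
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    eta <- matrix(stats::rnorm(n * t_frames, 0, noise_sd), n, t_frames)
    eta[, 1L] <- eta[, 1L] / sqrt(1 - ar_coefficient^2)
    if (ar_coefficient != 0 && t_frames > 1L) {
      eps <- eta
      for (t in 2L:t_frames) {
        eps[, t] <- ar_coefficient * eps[, t - 1L] + eta[, t]
      }
      x <- x + eps
    } else {
      x <- x + eta
    }
  }
  regional_time_series(subject_id, x, tr_seconds,
                       roi_labels = colnames(centroids))
}

#' Generate a modular weighted connectome
#'
#' Random symmetric nonnegative connectome with exactly zero diagonal.
#' Within-module edges are denser and carry stochastically larger
#' (log-normal) weights than between-module edges. Disconnected realizations
#' are regenerated with an incremented seed (logged via `message`).
#'
#' @param n_rois number of nodes, at least 2.
#' @param module_partition a [parcellation_table()] giving each node's
#'   module; defaults to a single module.
#' @param seed integer seed.
#' @param p_within,p_between edge probabilities within/between modules.
#' @param meanlog_within,meanlog_between log-normal location parameters.
#' @param sdlog log-normal scale parameter.
#' @param subject_id identifier for the resulting connectome.
#' @return A [connectome()].
#' @export
generate_connectome <- function(n_rois, module_partition = NULL, seed = 1L,
                                p_within = 0.85, p_between = 0.35,
                                meanlog_within = 1, meanlog_between = 0,
                                sdlog = 0.5, subject_id = "synthetic") {
  stopifnot(n_rois >= 2L)
  if (is.null(module_partition)) {
    modules <- rep("M1", n_rois)
    labels <- paste0("ROI", seq_len(n_rois))
  } else {
    stopifnot(nrow(module_partition) == n_rois)
    modules <- module_partition$network
    labels <- module_partition$roi_label
  }
  same <- outer(modules, modules, "==")
  ut <- upper.tri(same)
  seed <- as.integer(seed)
  repeat {
    set.seed(seed)
    n_edges <- sum(ut)
    p_edge <- ifelse(same[ut], p_within, p_between)
    present <- stats::runif(n_edges) < p_edge
    w <- ifelse(present,
                stats::rlnorm(n_edges,
                              meanlog = ifelse(same[ut], meanlog_within,
                                               meanlog_between),
                              sdlog = sdlog),
                0)
    a <- matrix(0, n_rois, n_rois)
    a[ut] <- w
    a <- a + t(a)
    g <- igraph::graph_from_adjacency_matrix(a > 0, mode = "undirected")
    if (igraph::is_connected(g)) break
    message("generate_connectome: disconnected realization at seed ", seed,
            "; regenerating with seed ", seed + 1L)
    seed <- seed + 1L
  }
  connectome(subject_id, a, roi_labels = labels)
}

#' Generate a full synthetic cohort with ground truth
#'
#' Produces, for each subject in two groups: a Markov state sequence from the
#' group's planted transition matrix, a BOLD series emitted from planted
#' centroid patterns with AR(1) noise, a modular structural connectome, and
#' clinical scores whose means are linearly coupled to the subject's planted
#' fractional occupancy (percent) of the designated state. Everything is a
#' deterministic function of `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return A list with elements
#'   \describe{
#'     \item{time_series}{list of [regional_time_series()], HC then MDD}
#'     \item{connectomes}{list of [connectome()] in the same order}
#'     \item{clinical}{clinical `data.frame` (`subject`, `group`, `age`,
#'       `sex`, `medication`, seven score columns)}
#'     \item{parcellation}{the [parcellation_table()] used}
#'     \item{ground_truth}{list: `centroids`, `state_sequences`,
#'       `realized_transition_matrices` (per group, row-stochastic, includes
#'       self-transitions), `planted_occupancy` (percent, per subject, for
#'       `coupled_state`), `group`, `config`}
#'   }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  parc <- default_parcellation(config$n_rois)
  cent <- generate_state_patterns(config$k_states, config$n_rois, parc,
                                  seed = config$seed)
  groups <- rep(c("HC", "MDD"), each = config$n_subjects_per_group)
  n_sub <- length(groups)
  ids <- sprintf("sub-%03d", seq_len(n_sub))
  seq_seeds <- config$seed + 1000L + seq_len(n_sub)
  bold_seeds <- config$seed + 2000L + seq_len(n_sub)
  conn_seeds <- config$seed + 3000L + 10L * seq_len(n_sub)
  ts <- vector("list", n_sub)
  conns <- vector("list", n_sub)
  seqs <- vector("list", n_sub)
  fo <- numeric(n_sub)
  for (i in seq_len(n_sub)) {
    P <- config$group_transition_matrices[[groups[i]]]
    seqs[[i]] <- simulate_state_sequence(P, config$frames_per_subject,
                                         seed = seq_seeds[i])
    ts[[i]] <- emit_bold(seqs[[i]], cent, config$ar_coefficient,
                         config$noise_sd, seed = bold_seeds[i],
                         tr_seconds = config$tr_seconds, subject_id = ids[i])
    conns[[i]] <- generate_connectome(config$n_rois, parc,
                                      seed = conn_seeds[i],
                                      subject_id = ids[i])
    fo[i] <- 100 * mean(seqs[[i]] == config$coupled_state)
  }
  # realized (empirical, pooled within group) conditional transition matrices
  realized <- lapply(c(HC = "HC", MDD = "MDD"), function(g) {
    counts <- matrix(0, config$k_states, config$k_states)
    for (i in which(groups == g)) {
      s <- seqs[[i]]
      for (t in seq_len(length(s) - 1L)) {
        counts[s[t], s[t + 1L]] <- counts[s[t], s[t + 1L]] + 1
      }
    }
    counts / pmax(rowSums(counts), 1)
  })
  set.seed(config$seed + 4000L)
  age <- round(stats::rnorm(n_sub, mean = ifelse(groups == "HC", 30.8, 28.1),
                            sd = 7), 1)
  sex <- stats::rbinom(n_sub, 1L, 0.5)
  medication <- ifelse(groups == "MDD", stats::rbinom(n_sub, 1L, 0.5), 0L)
  base_means <- c(QIDS = 8, MASQ_AD = 55, MASQ_AA = 25, MASQ_GD = 20,
                  RRS_DEP = 25, RRS_BRO = 10, RRS_REF = 10)
  clin <- data.frame(subject = ids, group = groups, age = age, sex = sex,
                     medication = medication, stringsAsFactors = FALSE)
  fo_centered <- fo - mean(fo)
  for (s in names(config$clinical_coupling)) {
    clin[[s]] <- base_means[[s]] + config$clinical_coupling[[s]] * fo_centered +
      stats::rnorm(n_sub, 0, config$clinical_noise_sd)
  }
  clinical_table(clin)
  list(time_series = ts,
       connectomes = conns,
       clinical = clin,
       parcellation = parc,
       ground_truth = list(
         centroids = cent,
         state_sequences = stats::setNames(seqs, ids),
         realized_transition_matrices = realized,
         planted_occupancy = stats::setNames(fo, ids),
         group = stats::setNames(groups, ids),
         config = config))
}

#' Write a synthetic cohort bundle to disk
#'
#' Writes per-subject BOLD matrices and connectomes as tab-delimited text,
#' the clinical and parcellation tables as CSV, and the ground truth (planted
#' centroids, per-group realized transition matrices, planted occupancies) as
#' JSON.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ts in cohort$time_series) {
    write_matrix(ts$matrix, file.path(dir, paste0(ts$subject_id, "_bold.tsv")))
  }
  for (cn in cohort$connectomes) {
    write_matrix(cn$weights,
                 file.path(dir, paste0(cn$subject_id, "_connectome.tsv")))
  }
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$parcellation, file.path(dir, "parcellation.csv"),
                   row.names = FALSE)
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(centroids = unclass(gt$centroids),
         realized_transition_matrices = gt$realized_transition_matrices,
         planted_occupancy = as.list(gt$planted_occupancy),
         group = as.list(gt$group),
         tr_seconds = gt$config$tr_seconds,
         k_states = gt$config$k_states,
         seed = gt$config$seed),
    file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
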