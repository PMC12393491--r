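#' Per-subject state sequence
#'
#' Frame-wise state labels for one subject, the substrate of all temporal
#' dynamics metrics. Transitions are never counted across subjects because
#' each sequence is scored on its own.
#'
#' @param subject_id character scalar.
#' @param labels integer labels in `1..k`.
#' @param k number of states.
#' @param tr_seconds repetition time (seconds).
#' @return Object of class `state_sequence`.
#' @export
state_sequence <- function(subject_id, labels, k, tr_seconds) {
  labels <- as.integer(labels)
  stopifnot(length(labels) >= 1L, tr_seconds > 0, k >= 1L)
  if (any(labels < 1L | labels > k)) {
    stop("label outside 1..", k, " for subject '", subject_id, "'")
  }
  structure(list(subject_id = subject_id, labels = labels, k = as.integer(k),
                 tr_seconds = tr_seconds), class = "state_sequence")
}

#' Maximal constant runs of a label sequence
#'
#' @param labels integer label vector (nonempty).
#' @return List with `state` (state of each run, in order) and `length` (run
#'   lengths in frames). Lengths per state sum to that state's frame count.
#' @export
run_lengths <- function(labels) {
  stopifnot(length(labels) >= 1L)
  r <- rle(as.integer(labels))
  list(state = r$values, length = r$lengths)
}

#' Dwell time per state
#'
#' Mean duration, in seconds, of maximal consecutive runs of each state:
#' mean run length times TR. States never visited have no defined dwell time
#' and are reported as `NA` (missing, not zero), so they can be excluded from
#' group tests rather than biasing them.
#'
#' @param sequence a [state_sequence()].
#' @return Numeric vector of length `k` (seconds), `NA` for unvisited states.
#' @export
dwell_time <- function(sequence) {
  stopifnot(inherits(sequence, "state_sequence"))
  r <- run_lengths(sequence$labels)
  out <- rep(NA_real_, sequence$k)
  agg <- tapply(r$length, factor(r$state, levels = seq_len(sequence$k)), mean)
  out[!is.na(agg)] <- agg[!is.na(agg)] * sequence$tr_seconds
  out
}

#' Fractional occupancy per state
#'
#' Percentage of the scan's frames assigned to each state. Sums to 100.
#'
#' @param sequence a [state_sequence()].
#' @return Numeric vector of length `k` (percent).
#' @export
fractional_occupancy <- function(sequence) {
  stopifnot(inherits(sequence, "state_sequence"))
  100 * tabulate(sequence$labels, sequence$k) / length(sequence$labels)
}

#' Transition probabilities between states
#'
#' Counts frame pairs `(t, t+1)` whose label changes (self-transitions are
#' removed before counting) within one subject's sequence. Two
#' normalizations are available:
#' \describe{
#'   \item{`"joint"` (default)}{`P(i -> j) = N(i -> j) / N_switches`: each
#'     entry is the joint probability of observing that particular switch
#'     among all switches, so the off-diagonal entries sum to 1. Under this
#'     convention per-state exit/enter probabilities carry information about
#'     how often a state is switched out of or into.}
#'   \item{`"row"`}{`P(i -> j) = N(i -> j) / N(i -> any)`: rows sum to 1
#'     where the state was exited at least once. Under this convention every
#'     state's exit probability is identically `1/(K-1)`.}
#' }
#' The diagonal is exactly zero. A sequence with no switches yields an
#' all-zero matrix with attribute `no_switches = TRUE`.
#'
#' @param sequence a [state_sequence()].
#' @param normalize `"joint"` or `"row"`.
#' @return `k x k` matrix with attributes `n_switches` and `no_switches`.
#' @export
transition_probabilities <- function(sequence, normalize = c("joint", "row")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(sequence, "state_sequence"))
  k <- sequence$k
  l <- sequence$labels
  from <- l[-length(l)]
  to <- l[-1L]
  keep <- from != to
  counts <- matrix(0, k, k)
  if (any(keep)) {
    tab <- table(factor(from[keep], levels = seq_len(k)),
                 factor(to[keep], levels = seq_len(k)))
    counts <- matrix(as.numeric(tab), k, k)
  }
  n_switches <- sum(counts)
  p <- if (n_switches == 0) {
    counts
  } else if (normalize == "joint") {
    counts / n_switches
  } else {
    sweep(counts, 1L, pmax(rowSums(counts), 1), "/")
  }
  diag(p) <- 0
  attr(p, "n_switches") <- as.integer(n_switches)
  attr(p, "no_switches") <- n_switches == 0
  p
}

#' Exit and enter probabilities of a state
#'
#' `exit(i)` is the mean of `P(i -> j)` over `j != i`; `enter(i)` is the mean
#' of `P(j -> i)` over `j != i`.
#'
#' @param p transition-probability matrix from [transition_probabilities()].
#' @param i state index; if missing, all states are returned.
#' @return Scalar (if `i` given) or vector of length `k`.
#' @export
exit_probability <- function(p, i) {
  k <- nrow(p)
  ex <- rowSums(p) / (k - 1)
  if (missing(i)) ex else ex[i]
}

#' @rdname exit_probability
#' @export
enter_probability <- function(p, i) {
  k <- nrow(p)
  en <- colSums(p) / (k - 1)
  if (missing(i)) en else en[i]
}

#' Per-subject dynamics summary
#'
#' Computes all temporal metrics for one state sequence: dwell times,
#' fractional occupancies, the transition-probability matrix, exit and enter
#' probabilities, and the switch count.
#'
#' @param sequence a [state_sequence()].
#' @param normalize passed to [transition_probabilities()].
#' @return List of class `dynamics_summary`.
#' @export
dynamics_summary <- function(sequence, normalize = "joint") {
  p <- transition_probabilities(sequence, normalize = normalize)
  structure(list(
    subject_id = sequence$subject_id,
    dwell_time = dwell_time(sequence),
    fractional_occupancy = fractional_occupancy(sequence),
    transition_probabilities = p,
    exit_probability = exit_probability(p),
    enter_probability = enter_probability(p),
    n_switches = attr(p, "n_switches")), class = "dynamics_summary")
}

#' Cohort-level dynamics table
#'
#' Applies [dynamics_summary()] to every subject and returns a long-format
#' table keyed by subject, metric and state (and target state for transition
#' probabilities).
#'
#' @param sequences list of [state_sequence()].
#' @param normalize passed to [transition_probabilities()].
#' @return data.frame with columns `subject`, `metric`, `from_state`,
#'   `to_state`, `value`.
#' @export
cohort_dynamics <- function(sequences, normalize = "joint") {
  rows <- lapply(sequences, function(sq) {
    s <- dynamics_summary(sq, normalize = normalize)
    k <- sq$k
    scalar <- data.frame(
      subject = s$subject_id,
      metric = rep(c("dwell_time", "fractional_occupancy",
                     "exit_probability", "enter_probability"), each = k),
      from_state = rep(seq_len(k), 4L),
      to_state = NA_integer_,
      value = c(s$dwell_time, s$fractional_occupancy,
                s$exit_probability, s$enter_probability))
    trans <- expand.grid(from_state = seq_len(k), to_state = seq_len(k))
    trans <- trans[trans$from_state != trans$to_state, ]
    trans <- data.frame(
      subject = s$subject_id, metric = "transition_probability",
      from_state = trans$from_state, to_state = trans$to_state,
      value = s$transition_probabilities[cbind(trans$from_state,
                                               trans$to_state)])
    rbind(scalar, trans)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run-permutation null for transition probabilities
#'
#' Builds a within-subject null by randomly permuting the order of the
#' sequence's maximal runs. The run-length multiset and per-state occupancy
#' are preserved exactly, so the null conditions on everything except the
#' order in which states follow each other. For each ordered state pair the
#' empirical two-sided or one-sided p-value of the observed transition
#' probability is reported with the add-one convention
#' `p = (1 + #extreme) / (1 + n_perm)`.
#'
#' @param sequence a [state_sequence()].
#' @param n_perm number of permutations (at least 100).
#' @param seed integer seed.
#' @param alternative `"greater"` (observed larger than null) or
#'   `"two.sided"`.
#' @param normalize passed to [transition_probabilities()].
#' @return List: `observed` (`k x k`), `p_values` (`k x k`, diagonal `NA`),
#'   `null_mean`, `n_perm`, `skipped` (TRUE when fewer than 3 runs).
#' @export
permutation_null_transitions <- function(sequence, n_perm = 1000L, seed = 1L,
                                         alternative = c("greater", "two.sided"),
                                         normalize = "joint") {
  alternative <- match.arg(alternative)
  if (n_perm < 100L) stop("n_perm must be at least 100, got ", n_perm)
  r <- run_lengths(sequence$labels)
  if (length(r$state) < 3L) {
    return(list(observed = transition_probabilities(sequence, normalize),
                p_values = NULL, null_mean = NULL, n_perm = n_perm,
                skipped = TRUE))
  }
  obs <- transition_probabilities(sequence, normalize)
  k <- sequence$k
  set.seed(as.integer(seed))
  ge <- matrix(0, k, k)
  le <- matrix(0, k, k)
  null_sum <- matrix(0, k, k)
  for (b in seq_len(n_perm)) {
    ord <- sample.int(length(r$state))
    perm_labels <- rep(r$state[ord], r$length[ord])
    pseq <- state_sequence(sequence$subject_id, perm_labels, k,
                           sequence$tr_seconds)
    pn <- transition_probabilities(pseq, normalize)
    ge <- ge + (pn >= obs)
    le <- le + (pn <= obs)
    null_sum <- null_sum + pn
  }
  null_mean <- null_sum / n_perm
  p <- (1 + ge) / (1 + n_perm)
  if (alternative == "two.sided") {
    p <- pmin(1, 2 * pmin((1 + ge) / (1 + n_perm), (1 + le) / (1 + n_perm)))
  }
  diag(p) <- NA_real_
  list(observed = obs, p_values = p, null_mean = null_mean,
       n_perm = as.integer(n_perm), skipped = FALSE)
}

#' Build per-subject state sequences from a clustering solution
#'
#' Splits the concatenated frame labels back into per-subject sequences using
#' the dataset's frame-to-subject map, so no dynamics metric ever crosses a
#' subject boundary.
#'
#' @param solution a `cluster_solution` from [kmedoids()].
#' @param dataset the `concatenated_dataset` that was clustered.
#' @return Named list of [state_sequence()], in first-appearance order.
#' @export
split_state_sequences <- function(solution, dataset) {
  stopifnot(inherits(dataset, "concatenated_dataset"),
            length(solution$labels) == length(dataset$frame_subject_index))
  idx <- dataset$frame_subject_index
  ids <- unique(idx)
  out <- lapply(ids, function(id) {
    state_sequence(id, solution$labels[idx == id], solution$k,
                   dataset$tr_seconds)
  })
  stats::setNames(out, ids)
}
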