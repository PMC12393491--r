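#' Normalize a connectome into a stable linear system
#'
#' Scales the adjacency matrix and shifts its spectrum so that the
#' continuous-time dynamics `dx/dt = A x + B u` are stable:
#' `A_norm = A / (lambda_max(A) + c) - I`. With `c > 0` every eigenvalue of
#' `A_norm` has a strictly negative real part (for a symmetric nonnegative
#' `A`, the spectrum lies in `[-2, 0)`). Because `c` is an absolute offset,
#' connectomes should be compared on a common weight scale; energies carry
#' arbitrary units in any case.
#'
#' @param conn a [connectome()] or a symmetric nonnegative zero-diagonal
#'   matrix.
#' @param c positive stabilization constant (default 1).
#' @return Object of class `normalized_system` with fields `a_norm`,
#'   `normalization_constant`, `source_connectome_id`.
#' @export
normalize_adjacency <- function(conn, c = 1) {
  stopifnot(c > 0)
  if (inherits(conn, "connectome")) {
    a <- conn$weights
    id <- conn$subject_id
  } else {
    a <- as.matrix(conn)
    id <- "matrix"
    if (max(abs(a - t(a))) > 1e-9) stop("adjacency must be symmetric")
    if (any(diag(a) != 0)) stop("adjacency diagonal must be zero")
    if (any(a < 0)) stop("adjacency must be nonnegative")
  }
  if (all(a == 0)) stop("all-zero adjacency cannot be normalized")
  lam <- max(eigen(a, symmetric = TRUE, only.values = TRUE)$values)
  a_norm <- a / (lam + c) - diag(nrow(a))
  structure(list(a_norm = a_norm, normalization_constant = c,
                 source_connectome_id = id), class = "normalized_system")
}

#' Optimal control task specification
#'
#' Parameters of the linear-quadratic steering problem: minimize
#' `integral_0^T [ (x - xf)' S (x - xf) + rho * u'u ] dt` subject to
#' `dx/dt = A x + B u`, `x(0) = x0`, `x(T) = xf`. The defaults — horizon
#' `T = 1`, `rho = 1`, `B` the identity (uniform full control set), `S` the
#' identity (full trajectory constraint) — are the standard optimal-control
#' configuration for state transitions on brain networks.
#'
#' @param x0,xf initial and target state vectors (z-units).
#' @param horizon_t positive time horizon.
#' @param rho positive control-effort weight.
#' @param control_set_b `N x m` control input matrix; default identity.
#' @param state_cost_s `N x N` positive semidefinite trajectory-cost matrix;
#'   default identity.
#' @param n_time_steps number of trajectory sample points (at least 2).
#' @return Object of class `control_task`.
#' @export
control_task <- function(x0, xf, horizon_t = 1, rho = 1,
                         control_set_b = NULL, state_cost_s = NULL,
                         n_time_steps = 1001L) {
  n <- length(x0)
  stopifnot(length(xf) == n, all(is.finite(x0)), all(is.finite(xf)),
            horizon_t > 0, rho > 0, n_time_steps >= 2L)
  if (is.null(control_set_b)) control_set_b <- diag(n)
  if (is.null(state_cost_s)) state_cost_s <- diag(n)
  stopifnot(nrow(control_set_b) == n, nrow(state_cost_s) == n,
            ncol(state_cost_s) == n)
  structure(list(x0 = as.numeric(x0), xf = as.numeric(xf),
                 horizon_t = horizon_t, rho = rho,
                 control_set_b = control_set_b, state_cost_s = state_cost_s,
                 n_time_steps = as.integer(n_time_steps)),
            class = "control_task")
}

expm_dense <- function(m) {
  as.matrix(Matrix::expm(Matrix::Matrix(m)))
}

#' Solve the optimal control problem for one state transition
#'
#' Solves the linear-quadratic two-point boundary-value problem exactly via
#' the Hamiltonian block system. With costate `p`, the optimality conditions
#' are `u = -B'p / (2 rho)` and
#' `d/dt [x; p] = [[A, -BB'/(2 rho)], [-2S, -A']] [x; p] + [0; 2 S xf]`;
#' the costate's initial value is obtained from the matrix exponential of the
#' augmented system by enforcing `x(T) = xf`, and the trajectory is then
#' propagated with a fixed-step exponential integrator (exact for this
#' linear system). Nodal energy is the composite-trapezoid integral of
#' `u_i(t)^2`; the total energy is their sum.
#'
#' @param system a [normalize_adjacency()] result (or any object with a
#'   stable `a_norm` matrix).
#' @param task a [control_task()].
#' @param terminal_tol terminal-constraint tolerance, scaled by
#'   `1 + ||xf||`; exceeding it is an error.
#' @return Object of class `control_result`: `trajectory`
#'   (`n_time_steps x N`), `controls` (`n_time_steps x m`), `times`,
#'   `nodal_energy` (length m), `total_energy`, `terminal_error`.
#' @export
solve_optimal_control <- function(system, task, terminal_tol = 1e-6) {
  a <- system$a_norm
  n <- nrow(a)
  if (max(Re(eigen(a, only.values = TRUE)$values)) >= 0) {
    stop("system matrix is not stable")
  }
  b <- task$control_set_b
  s <- task$state_cost_s
  rho <- task$rho
  tt <- task$horizon_t
  m <- ncol(b)
  ham <- rbind(cbind(a, -tcrossprod(b) / (2 * rho)),
               cbind(-2 * s, -t(a)))
  const <- c(numeric(n), 2 * s %*% task$xf)
  aug <- rbind(cbind(ham, const), 0)
  big <- expm_dense(aug * tt)
  e11 <- big[seq_len(n), seq_len(n), drop = FALSE]
  e12 <- big[seq_len(n), n + seq_len(n), drop = FALSE]
  d1 <- big[seq_len(n), 2L * n + 1L]
  rc <- rcond(e12)
  if (rc < .Machine$double.eps * 100) {
    stop("boundary block is numerically singular (reciprocal condition ",
         signif(rc, 3), "): target unreachable within the horizon")
  }
  p0 <- solve(e12, task$xf - e11 %*% task$x0 - d1)
  n_t <- task$n_time_steps
  dt <- tt / (n_t - 1L)
  step <- expm_dense(aug * dt)
  z <- c(task$x0, p0, 1)
  traj <- matrix(NA_real_, n_t, n)
  ctrl <- matrix(NA_real_, n_t, m)
  bt_fac <- -t(b) / (2 * rho)
  traj[1L, ] <- task$x0
  ctrl[1L, ] <- bt_fac %*% z[n + seq_len(n)]
  for (t in 2L:n_t) {
    z <- step %*% z
    traj[t, ] <- z[seq_len(n)]
    ctrl[t, ] <- bt_fac %*% z[n + seq_len(n)]
  }
  terminal_error <- sqrt(sum((traj[n_t, ] - task$xf)^2))
  tol <- terminal_tol * (1 + sqrt(sum(task$xf^2)))
  if (terminal_error > tol) {
    stop("terminal constraint violated: ||x(T) - xf|| = ",
         signif(terminal_error, 6), " > tolerance ", signif(tol, 6))
  }
  u2 <- ctrl^2
  w <- rep(dt, n_t)
  w[c(1L, n_t)] <- dt / 2
  nodal <- as.numeric(crossprod(u2, w))
  structure(list(trajectory = traj, controls = ctrl,
                 times = seq(0, tt, length.out = n_t),
                 nodal_energy = nodal, total_energy = sum(nodal),
                 terminal_error = terminal_error), class = "control_result")
}

#' Direct-minimization reference for the optimal control energy
#'
#' Brute-force check of [solve_optimal_control()]: the control signal is
#' restricted to be piecewise constant over `n_segments` equal segments, the
#' state is propagated exactly under each segment (zero-order hold), the
#' quadratic cost (trapezoid rule for the state term) is minimized over all
#' segment values subject to the linear terminal constraint by solving the
#' KKT system directly. Returns the energy `integral u'u dt` of the
#' discretized minimizer; as `n_segments` grows this converges to the
#' continuous optimum from above. Intended for small systems (`N <= 3`).
#'
#' @param system a `normalized_system` (or list with `a_norm`).
#' @param task a [control_task()].
#' @param n_segments number of piecewise-constant control segments.
#' @return List: `total_energy`, `controls` (`n_segments x m`).
#' @export
discretized_control_energy <- function(system, task, n_segments = 500L) {
  a <- system$a_norm
  n <- nrow(a)
  b <- task$control_set_b
  m <- ncol(b)
  s <- task$state_cost_s
  rho <- task$rho
  tt <- task$horizon_t
  dt <- tt / n_segments
  ad <- expm_dense(a * dt)
  bd <- solve(a, (ad - diag(n)) %*% b)   # stable => A invertible
  # impulse-response stack: R_l = ad^l %*% bd, l = 0..n_segments-1
  tall <- matrix(0, n_segments * n, m)
  r_l <- bd
  for (l in seq_len(n_segments)) {
    tall[(l - 1L) * n + seq_len(n), ] <- r_l
    r_l <- ad %*% r_l
  }
  n_pts <- n_segments + 1L
  g <- matrix(0, n_pts * n, n_segments * m)
  for (seg in seq_len(n_segments)) {
    rows <- (seg * n + 1L):(n_pts * n)
    g[rows, (seg - 1L) * m + seq_len(m)] <-
      tall[seq_len((n_segments - seg + 1L) * n), , drop = FALSE]
  }
  # free trajectory and targets at the sample points
  phi_x0 <- matrix(0, n_pts, n)
  xk <- task$x0
  phi_x0[1L, ] <- xk
  for (t in 2L:n_pts) {
    xk <- ad %*% xk
    phi_x0[t, ] <- xk
  }
  resid0 <- as.numeric(t(phi_x0)) - rep(task$xf, n_pts)  # stacked x_t - xf
  w_t <- rep(dt, n_pts)
  w_t[c(1L, n_pts)] <- dt / 2
  s_half <- chol_psd(s)
  w_half <- kronecker(diag(sqrt(w_t)), s_half)            # sqrt of blockdiag W
  gw <- w_half %*% g
  h <- 2 * (crossprod(gw) + rho * dt * diag(n_segments * m))
  grad <- 2 * as.numeric(crossprod(gw, w_half %*% resid0))
  lhs_term <- g[((n_segments) * n + 1L):(n_pts * n), , drop = FALSE]
  rhs_term <- task$xf - phi_x0[n_pts, ]
  kkt <- rbind(cbind(h, t(lhs_term)),
               cbind(lhs_term, matrix(0, n, n)))
  sol <- solve(kkt, c(-grad, rhs_term))
  u <- matrix(sol[seq_len(n_segments * m)], n_segments, m, byrow = TRUE)
  list(total_energy = dt * sum(u^2), controls = u)
}

chol_psd <- function(s) {
  # square root of a PSD matrix (handles S = 0 and rank deficiency)
  e <- eigen(s, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Transition energy matrix between brain states
#'
#' Entry `(i, j)` is the total optimal-control energy for steering the system
#' from state `i`'s activation pattern to state `j`'s. The diagonal
#' (self-maintenance energy: opposing the decay of a nonzero pattern) is
#' computed but excluded from exit/enter summaries. Solve failures leave the
#' entry `NA` with a message; the run continues.
#'
#' @param conn a [connectome()] or [normalize_adjacency()] result.
#' @param centroids `K x N` matrix of state patterns (rows).
#' @param horizon_t,rho,n_time_steps task parameters, see [control_task()].
#' @param norm_c stabilization constant when `conn` is a raw connectome.
#' @param state_scale `"raw"` (default) uses centroids as given; `"unit"`
#'   rescales each to unit Euclidean norm (energy scales quadratically with
#'   state magnitude).
#' @return List of class `transition_energy`: `total` (`K x K`), `nodal`
#'   (`K x K x N`), `terminal_errors` (`K x K`).
#' @export
transition_energy_matrix <- function(conn, centroids, horizon_t = 1, rho = 1,
                                     n_time_steps = 1001L, norm_c = 1,
                                     state_scale = c("raw", "unit")) {
  state_scale <- match.arg(state_scale)
  system <- if (inherits(conn, "normalized_system")) conn else
    normalize_adjacency(conn, c = norm_c)
  k <- nrow(centroids)
  n <- ncol(centroids)
  stopifnot(n == nrow(system$a_norm))
  if (state_scale == "unit") {
    centroids <- centroids / sqrt(rowSums(centroids^2))
  }
  total <- matrix(NA_real_, k, k)
  terr <- matrix(NA_real_, k, k)
  nodal <- array(NA_real_, c(k, k, n))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      res <- tryCatch(
        solve_optimal_control(
          system,
          control_task(centroids[i, ], centroids[j, ], horizon_t = horizon_t,
                       rho = rho, n_time_steps = n_time_steps)),
        error = function(e) {
          message("transition_energy_matrix: transition ", i, " -> ", j,
                  " failed (", conditionMessage(e), ")")
          NULL
        })
      if (!is.null(res)) {
        total[i, j] <- res$total_energy
        terr[i, j] <- res$terminal_error
        nodal[i, j, ] <- res$nodal_energy
      }
    }
  }
  structure(list(total = total, nodal = nodal, terminal_errors = terr),
            class = "transition_energy")
}

#' Exit/enter energies and the energy-landscape classification
#'
#' `exit(i)` is the mean of row `i`'s off-diagonal transition energies,
#' `enter(i)` the mean of column `i`'s. A state with `exit > enter` sits in a
#' local minimum of the landscape (sink-like: leaving costs more than
#' arriving); `exit < enter` marks a local maximum (source-like).
#' `depth_rank` orders all states by `(exit + enter) / 2` ascending, so
#' higher ranks correspond to energetically deeper/higher positions.
#'
#' @param energy_matrix `K x K` total-energy matrix (from
#'   [transition_energy_matrix()], field `total`) or a `transition_energy`.
#' @param tol relative tolerance below which `exit == enter` is flagged
#'   degenerate.
#' @return data.frame of class `energy_landscape`: `state`, `exit_energy`,
#'   `enter_energy`, `classification`, `depth_rank`; attribute
#'   `has_missing` when NA entries were averaged around.
#' @export
exit_enter_energies <- function(energy_matrix, tol = 1e-12) {
  e <- if (inherits(energy_matrix, "transition_energy")) energy_matrix$total
       else as.matrix(energy_matrix)
  k <- nrow(e)
  stopifnot(k >= 2L, ncol(e) == k)
  off <- e
  diag(off) <- NA_real_
  has_missing <- anyNA(off[row(off) != col(off)])
  exit <- rowMeans(off, na.rm = TRUE)
  enter <- colMeans(off, na.rm = TRUE)
  degen <- !is.na(exit) & !is.na(enter) &
    abs(exit - enter) <= tol * pmax(abs(exit) + abs(enter), 1)
  cls <- ifelse(degen, "degenerate",
                ifelse(exit > enter, "sink-like", "source-like"))
  if (any(degen)) {
    message("exit_enter_energies: exit == enter for state(s) ",
            paste(which(degen), collapse = ", "), "; classification degenerate")
  }
  out <- data.frame(state = seq_len(k), exit_energy = exit,
                    enter_energy = enter, classification = cls,
                    depth_rank = rank((exit + enter) / 2, ties.method = "min"))
  attr(out, "has_missing") <- has_missing
  class(out) <- c("energy_landscape", "data.frame")
  out
}
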