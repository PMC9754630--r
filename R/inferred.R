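# Two-dimensional DP for the inferred reward-change task: the observer
# tracks both the choice belief p and the reward belief q = Pr(R = R_high),
# inferred from an independent evidence stream through a sinh-nonlinearity
# diffusion.

#' Reward-belief transfer matrix
#'
#' One-step transfer of the reward belief q under an Euler discretization of
#' \eqn{dy_R = x(t) m_R dt - 2h\sinh(y_R)dt + \sqrt{2m_R}\,dW}: a
#' two-component Gaussian mixture in \eqn{y_R} (the latent reward state is
#' high with probability q), changed to q-coordinates and discretized on the
#' grid with trapezoid weights and row renormalization.  When `m_R = 0` the
#' step is the deterministic hazard decay, discretized by linear
#' interpolation between neighbouring grid points.
#'
#' @param grid A [belief_grid()] over q.
#' @param proc A [reward_process_model()].
#' @param delta_t Time step.
#' @return A row-stochastic `transfer_matrix` over the q grid.
#' @export
build_reward_transfer_matrix <- function(grid, proc, delta_t) {
  stopifnot(inherits(grid, "belief_grid"), inherits(proc, "reward_process_model"))
  q <- grid$points
  n <- length(q)
  y <- grid$llr_points
  # the sinh drift is stiff: clamp the Euler step so it never overshoots the
  # fixed point at y = 0
  drift0 <- -sign(y) * pmin(2 * proc$hazard * sinh(abs(y)) * delta_t, abs(y))
  M <- matrix(0, n, n)
  if (proc$m_R == 0) {
    y_new <- y + drift0
    for (i in seq_len(n)) {
      j <- findInterval(y_new[i], y, all.inside = TRUE)
      w <- (y_new[i] - y[j]) / (y[j + 1L] - y[j])
      w <- min(max(w, 0), 1)
      M[i, j] <- 1 - w
      M[i, j + 1L] <- M[i, j + 1L] + w
    }
  } else {
    sd_y <- sqrt(2 * proc$m_R * delta_t)
    jac <- 1 / (q * (1 - q))
    half <- (n + 1L) %/% 2L
    for (i in seq_len(half)) {
      mu_hi <- min(max(y[i] + drift0[i] + proc$m_R * delta_t, y[1]), y[n])
      mu_lo <- min(max(y[i] + drift0[i] - proc$m_R * delta_t, y[1]), y[n])
      mix <- q[i] * dnorm(y, mu_hi, sd_y) + (1 - q[i]) * dnorm(y, mu_lo, sd_y)
      row <- mix * jac * grid$weights
      s <- sum(row)
      if (is.finite(s) && s > 0) {
        M[i, ] <- row / s
      } else {
        # density underflow at a saturated belief: point masses at the
        # grid points nearest the two clamped destinations
        M[i, which.min(abs(y - mu_hi))] <- q[i]
        j <- which.min(abs(y - mu_lo))
        M[i, j] <- M[i, j] + 1 - q[i]
      }
    }
    M[half, ] <- (M[half, ] + rev(M[half, ])) / 2
    for (i in seq.int(half + 1L, n)) M[i, ] <- rev(M[n + 1L - i, ])
  }
  structure(M, class = c("transfer_matrix", "matrix"), grid = grid, model = proc)
}

#' Solve the inferred reward-change task
#'
#' Backward induction on the joint (p, q) belief grid with commitment values
#' using the expected reward \eqn{R_H q + R_L(1 - q)}, co-optimizing the
#' reward rate as in the one-dimensional tasks (consistency at the start
#' state p = q = 1/2).
#'
#' @param context A `context_schedule` of kind `"inferred"` from
#'   [make_inferred_reward_context()].
#' @param np,nq Grid sizes for the choice belief p and reward belief q.
#' @param tol Tolerance on the start-value residual, scaled by
#'   `max(1, R_high)`.
#' @param full If `TRUE`, record the per-timestep upper threshold in p for
#'   every q.
#' @return A `value_solution` of kind `"inferred"` with `rho`, `v0`, and
#'   (if `full`) `thr_upper_p`: an (timesteps x nq) matrix of likelihood
#'   thresholds, `Inf` where waiting is optimal at all p.
#' @export
solve_inferred_reward <- function(context, np = 201L, nq = 101L,
                                  tol = 1e-6, full = TRUE) {
  stopifnot(context$kind == "inferred")
  proc <- context$proc
  dt <- context$delta_t
  n_steps <- round(context$t_final / dt)
  grid_p <- belief_grid(np)
  grid_q <- belief_grid(nq)
  Mp <- unclass(build_transfer_matrix(
    grid_p, evidence_model(piecewise_eval(context$mu, 0), context$sigma, dt)))
  Mq <- unclass(build_reward_transfer_matrix(grid_q, proc, dt))
  cost <- context_cost(context, 0)
  iti <- context$iti
  scale <- max(1, abs(proc$R_high), abs(proc$R_low))
  g <- function(rho) {
    cpp_backward_pass_2d(Mp, Mq, grid_p$points, grid_q$points,
                         proc$R_high, proc$R_low, context$reward_incorrect,
                         iti * rho, (cost + rho) * dt, n_steps, FALSE)$v0
  }
  lower <- (min(0, context$reward_incorrect) - cost * context$t_final) / iti
  upper <- scale / iti + 1e-3
  root <- find_rho_root(g, lower, upper, tol_g = tol * scale)
  res <- cpp_backward_pass_2d(Mp, Mq, grid_p$points, grid_q$points,
                              proc$R_high, proc$R_low, context$reward_incorrect,
                              iti * root$rho, (cost + root$rho) * dt,
                              n_steps, full)
  out <- list(kind = "inferred", v0 = res$v0, rho = root$rho,
              t = dt * (0:n_steps), grid = grid_p, grid_q = grid_q,
              context = context,
              rho_trace = list(evals = root$evals, residual = root$g))
  if (full) {
    thr <- res$thr_upper_p
    thr[is.nan(thr)] <- Inf
    out$thr_upper_p <- thr
  }
  structure(out, class = "value_solution")
}

#' Simulate the reward belief under a telegraph reward process
#'
#' Forward Euler simulation of the sinh-diffusion for the reward belief
#' \eqn{y_R}, driven by a latent telegraph process x(t) with hazard `h`.
#' Used to check that the inferred-reward belief tracks the latent reward
#' state.
#'
#' @param proc A [reward_process_model()].
#' @param horizon Simulation length (time units).
#' @param delta_t Euler step.
#' @param seed Optional integer seed.
#' @return A data.frame with columns `t`, `x` (latent state, +1 = high) and
#'   `y_r` (reward-belief LLR).
#' @export
simulate_reward_belief <- function(proc, horizon, delta_t = 0.01, seed = NULL) {
  stopifnot(inherits(proc, "reward_process_model"))
  if (!is.null(seed)) set.seed(seed)
  n <- ceiling(horizon / delta_t)
  x <- numeric(n + 1L)
  y <- numeric(n + 1L)
  x[1] <- sample(c(-1, 1), 1L)
  flip <- runif(n) < proc$hazard * delta_t
  z <- rnorm(n)
  for (k in seq_len(n)) {
    x[k + 1L] <- if (flip[k]) -x[k] else x[k]
    # the sinh drift is stiff: clamp the Euler step so the leak never
    # overshoots y = 0 (the belief is saturated at large |y| anyway)
    leak <- sign(y[k]) * min(2 * proc$hazard * sinh(abs(y[k])) * delta_t,
                             abs(y[k]))
    y[k + 1L] <- y[k] + x[k] * proc$m_R * delta_t - leak +
      sqrt(2 * proc$m_R * delta_t) * z[k]
  }
  data.frame(t = delta_t * (0:n), x = x, y_r = y)
}
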