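# Dynamic-programming solver: Bellman backward induction over the belief
# grid, reward-rate co-optimization, threshold extraction.

#' Transfer matrices for a continuous-evidence context
#'
#' Builds one likelihood transfer matrix per distinct evidence-quality piece
#' of the schedule and the per-timestep index that selects among them.
#'
#' @param context A `context_schedule` of kind `"continuous"`.
#' @param grid A [belief_grid()].
#' @return A list with `mats` (list of transfer matrices) and `piece`
#'   (integer index, one per backward-induction step).
#' @export
context_transfer_matrices <- function(context, grid = belief_grid()) {
  stopifnot(context$kind == "continuous")
  dt <- context$delta_t
  n_steps <- round(context$t_final / dt)
  mu_k <- context_mu(context, dt * (seq_len(n_steps) - 1L))
  mus <- unique(mu_k)
  mats <- lapply(mus, function(mu) {
    build_transfer_matrix(grid, evidence_model(mu, context$sigma, dt))
  })
  list(mats = mats, piece = match(mu_k, mus))
}

#' Terminal value of the Bellman recursion
#'
#' At the horizon it is impossible to wait for more evidence, so the value is
#' the better of the two commitments:
#' \eqn{V(p) = \max\{R_c p + R_i (1-p),\; R_c(1-p) + R_i p\} - \langle t_i\rangle\rho}.
#'
#' @param grid A [belief_grid()].
#' @param context A `context_schedule`.
#' @param rho Reward-rate penalty.
#' @return Numeric vector of terminal values at the grid points.
#' @export
terminal_value <- function(grid, context, rho) {
  p <- grid$points
  tf <- context$t_final
  Rc <- context_reward(context, tf)
  Ri <- context$reward_incorrect
  pen <- context_iti(context, tf) * rho
  pmax(Rc * p + Ri * (1 - p), Rc * (1 - p) + Ri * p) - pen
}

#' Bellman backward induction at a fixed reward rate
#'
#' Solves the value function
#' \eqn{V(p_n;\rho) = \max\{V_+, V_-, V_w\}} backward from the horizon,
#' where the commitment values are
#' \eqn{V_\pm = R_c p_\pm + R_i p_\mp - \langle t_i\rangle\rho} and the
#' waiting value is the transfer-matrix expectation of the next-step value
#' minus \eqn{c(t)\delta t + \rho\,\delta t}.  Ties are broken toward
#' commitment, and between commitments toward the side whose half of belief
#' space contains p.
#'
#' @param context A `context_schedule` (continuous or tokens).
#' @param rho Reward-rate penalty (use [solve_reward_rate()] to optimize it).
#' @param grid A [belief_grid()] (continuous contexts only).
#' @param transfer Optional precomputed [context_transfer_matrices()] result,
#'   reused across calls for speed.
#' @param full If `FALSE`, only the start value \eqn{V(p_0 = 1/2, t = 0)} is
#'   computed (used by the root finder).
#' @return A `value_solution`: value and action matrices (grid x time;
#'   actions 1 = choose s+, 2 = choose s-, 3 = wait), `rho`, time axis `t`,
#'   `v0`, and the inputs.
#' @export
backward_induction <- function(context, rho, grid = belief_grid(),
                               transfer = NULL, full = TRUE) {
  stopifnot(inherits(context, "context_schedule"))
  if (context$kind == "tokens") {
    return(tokens_backward_induction(context, rho, full = full))
  }
  if (context$kind != "continuous") {
    stop("use solve_inferred_reward() for the two-dimensional inferred-reward task")
  }
  dt <- context$delta_t
  n_steps <- round(context$t_final / dt)
  t <- dt * (0:n_steps)
  if (is.null(transfer)) transfer <- context_transfer_matrices(context, grid)
  p <- grid$points
  Rc <- context_reward(context, t)
  Ri <- context$reward_incorrect
  pen <- context_iti(context, t) * rho
  vplus <- outer(p, Rc) + outer(1 - p, rep(Ri, length(t))) -
    matrix(pen, length(p), length(t), byrow = TRUE)
  vminus <- outer(1 - p, Rc) + outer(p, rep(Ri, length(t))) -
    matrix(pen, length(p), length(t), byrow = TRUE)
  wait_sub <- context_cost(context, t[-length(t)]) * dt + rho * dt
  res <- cpp_backward_pass(lapply(transfer$mats, unclass), transfer$piece,
                           vplus, vminus, wait_sub, p, full)
  out <- list(kind = "continuous", v0 = res$v0, rho = rho, t = t,
              grid = grid, context = context)
  if (full) {
    out$value <- res$V
    out$action <- res$action
  }
  structure(out, class = "value_solution")
}

#' @export
print.value_solution <- function(x, ...) {
  cat(sprintf("value_solution (%s): rho = %.6g, V(1/2, 0) = %.3g, %d timesteps\n",
              x$kind, x$rho, x$v0, length(x$t)))
  invisible(x)
}

# Safeguarded secant/bisection root finder for the decreasing function
# g(rho) = V(1/2, 0; rho).  Keeps a sign-changing bracket at all times and
# clips secant steps into it.
find_rho_root <- function(g, lower, upper, tol_g, init = NULL,
                          max_iter = 80L) {
  glo <- g(lower)
  i <- 0L
  while (glo < 0 && i < 12L) {  # expand downward until g > 0
    upper <- lower
    lower <- lower - max(1, abs(lower)) * 2
    glo <- g(lower)
    i <- i + 1L
  }
  ghi <- g(upper)
  i <- 0L
  while (ghi > 0 && i < 12L) {
    lower <- upper
    glo <- ghi
    upper <- upper + max(1, abs(upper)) * 2
    ghi <- g(upper)
    i <- i + 1L
  }
  if (glo < 0 || ghi > 0) {
    stop("reward-rate root finding failed: no sign change in [",
         signif(lower, 6), ", ", signif(upper, 6), "] (g = ",
         signif(glo, 4), ", ", signif(ghi, 4), ")")
  }
  if (abs(glo) <= tol_g) return(list(rho = lower, g = glo, evals = i))
  if (abs(ghi) <= tol_g) return(list(rho = upper, g = ghi, evals = i))
  x0 <- lower; g0 <- glo; x1 <- upper; g1 <- ghi
  if (!is.null(init) && init > lower && init < upper) {
    gi <- g(init)
    if (abs(gi) <= tol_g) return(list(rho = init, g = gi, evals = i + 1L))
    if (gi > 0) { x0 <- init; g0 <- gi } else { x1 <- init; g1 <- gi }
  }
  side <- 0L
  for (iter in seq_len(max_iter)) {
    x <- x1 - g1 * (x1 - x0) / (g1 - g0)           # false position
    if (!is.finite(x) || x <= x0 || x >= x1) x <- (x0 + x1) / 2
    gx <- g(x)
    if (abs(gx) <= tol_g || (x1 - x0) < 1e-14 * max(1, abs(x))) {
      return(list(rho = x, g = gx, evals = iter))
    }
    if (gx > 0) {
      x0 <- x; g0 <- gx
      if (side == 1L) g1 <- g1 / 2                 # Illinois: unstick the
      side <- 1L                                   # stagnant endpoint
    } else {
      x1 <- x; g1 <- gx
      if (side == -1L) g0 <- g0 / 2
      side <- -1L
    }
  }
  list(rho = (x0 + x1) / 2, g = g((x0 + x1) / 2), evals = max_iter)
}

#' Co-optimize the trial-averaged reward rate
#'
#' The Bellman recursion is consistent only at the optimal reward rate, where
#' \eqn{V(p_0 = 1/2;\,\rho^*) = 0}.  Starting each trial from an
#' uninformative belief, the start value \eqn{g(\rho) = V(1/2, t = 0; \rho)}
#' is decreasing in \eqn{\rho} (every unit of \eqn{\rho} subtracts a
#' time-weighted penalty), so \eqn{\rho^*} is found by a safeguarded
#' secant/bisection scheme on a sign-changing bracket.
#'
#' @inheritParams backward_induction
#' @param rho_init Optional warm start (e.g. the solution of a neighbouring
#'   parameter cell).
#' @param tol Absolute tolerance on \eqn{|V(1/2, 0; \rho^*)|}, scaled by
#'   `max(1, max |reward|)`.
#' @return A `value_solution` with `rho` set to \eqn{\rho^*}; element
#'   `rho_trace` records the iteration count.
#' @export
solve_reward_rate <- function(context, grid = belief_grid(), transfer = NULL,
                              rho_init = NULL, tol = 1e-6, full = TRUE) {
  stopifnot(inherits(context, "context_schedule"))
  if (context$kind == "inferred") {
    return(solve_inferred_reward(context))
  }
  if (context$kind == "continuous" && is.null(transfer)) {
    transfer <- context_transfer_matrices(context, grid)
  }
  tgrid <- seq(0, context$t_final, by = context$delta_t)
  rmax <- max(abs(context_reward(context, tgrid)), abs(context$reward_incorrect))
  scale <- max(1, rmax)
  iti_min <- min(context_iti(context, tgrid))
  cost_max <- max(context_cost(context, tgrid))
  g <- function(rho) {
    backward_induction(context, rho, grid = grid, transfer = transfer,
                       full = FALSE)$v0
  }
  lower <- (min(0, context$reward_incorrect) - cost_max * context$t_final) /
    max(iti_min, 1e-6)
  upper <- rmax / max(iti_min, 1e-6) + 1e-3
  root <- find_rho_root(g, lower, upper, tol_g = tol * scale, init = rho_init)
  sol <- backward_induction(context, root$rho, grid = grid,
                            transfer = transfer, full = full)
  sol$rho_trace <- list(evals = root$evals, residual = root$g)
  sol
}

#' Extract time-varying decision thresholds from a value solution
#'
#' The decision thresholds are the belief values where the optimal action
#' switches from waiting to commitment: at each timestep the upper threshold
#' is the smallest grid likelihood where choosing \eqn{s_+} is optimal and
#' the lower one the largest where choosing \eqn{s_-} is optimal.  When
#' waiting is optimal at every grid point the threshold is infinite (the
#' observer will never respond at that time); the sentinel is `Inf` / `-Inf`.
#'
#' @param solution A `value_solution` from [backward_induction()] or
#'   [solve_reward_rate()] with `full = TRUE`.
#' @return A `threshold_trace`: data.frame with columns `t`,
#'   `theta_p_upper`, `theta_p_lower`, `theta_llr_upper`, `theta_llr_lower`,
#'   with attributes `window`, `change_times`, `grid_step` and (tokens) `n_t`
#'   (token lead at the upper threshold).
#' @export
extract_thresholds <- function(solution) {
  stopifnot(inherits(solution, "value_solution"))
  if (is.null(solution$action)) stop("solution was computed with full = FALSE")
  if (solution$kind == "tokens") return(tokens_extract_thresholds(solution))
  act <- solution$action
  p <- solution$grid$points
  up <- apply(act, 2, function(a) {
    i <- which(a == 1L)
    if (length(i)) p[i[1]] else Inf
  })
  lo <- apply(act, 2, function(a) {
    i <- which(a == 2L)
    if (length(i)) p[i[length(i)]] else -Inf
  })
  # at an exact commitment tie at p = 1/2 the tie rule assigns s+, but the
  # s- commitment boundary is 1/2 as well
  lo[up == 0.5] <- 0.5
  llr_up <- ifelse(is.finite(up), p_to_llr(pmin(pmax(up, 1e-12), 1 - 1e-12)), Inf)
  llr_lo <- ifelse(is.finite(lo), p_to_llr(pmin(pmax(lo, 1e-12), 1 - 1e-12)), -Inf)
  structure(
    data.frame(t = solution$t, theta_p_upper = up, theta_p_lower = lo,
               theta_llr_upper = llr_up, theta_llr_lower = llr_lo),
    class = c("threshold_trace", "data.frame"),
    window = solution$context$window,
    change_times = solution$context$change_times,
    grid_step = diff(p[1:2])
  )
}

#' @export
print.threshold_trace <- function(x, ...) {
  w <- attr(x, "window")
  fin <- is.finite(x$theta_p_upper[x$t <= w])
  cat(sprintf("threshold_trace: %d timesteps (%d infinite in window [0, %g])\n",
              nrow(x), sum(!fin), w))
  invisible(x)
}

#' Serialize a threshold trace as CSV
#'
#' Infinite-threshold sentinels are written as the literal string `"inf"`
#' (`"-inf"` for the lower trace).
#'
#' @param trace A `threshold_trace`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_threshold_csv <- function(trace, file) {
  df <- as.data.frame(trace)
  for (col in names(df)[-1]) {
    v <- df[[col]]
    df[[col]] <- ifelse(is.finite(v), trimws(format(v, digits = 10)),
                        ifelse(v > 0, "inf", "-inf"))
  }
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}
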