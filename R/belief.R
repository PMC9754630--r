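#' Belief grid over the state likelihood
#'
#' Discretizes the state likelihood \eqn{p = \Pr(s_+ \mid \xi_{1:n})} on a
#' symmetric grid in the open interval (0, 1).  The grid is the substrate for
#' the likelihood transfer matrices and the Bellman backward induction: value
#' functions are represented by their values at these points.  Each point has
#' a matched log-likelihood-ratio (LLR) coordinate
#' \eqn{y = \ln(p / (1 - p))}.
#'
#' @param n Number of grid points (odd, so that p = 0.5 is a grid point).
#' @param epsilon Clipping margin: the grid spans \[epsilon, 1 - epsilon\].
#'   The LLR is unbounded, so beliefs are represented in likelihood space and
#'   clipped away from 0 and 1.
#' @return An object of class `belief_grid` with elements `points`
#'   (likelihoods, strictly increasing, symmetric about 0.5), `llr_points`,
#'   `epsilon`, and trapezoid quadrature `weights`.
#' @examples
#' g <- belief_grid(101)
#' all.equal(g$points, rev(1 - g$points))
#' @export
belief_grid <- function(n = 501L, epsilon = 1e-4) {
  n <- as.integer(n)
  if (n < 3L) stop("belief grid needs at least 3 points")
  if (n %% 2L == 0L) stop("belief grid size must be odd so that p = 0.5 is a grid point")
  if (epsilon <= 0 || epsilon >= 0.5) stop("epsilon must lie in (0, 0.5)")
  p <- seq(epsilon, 1 - epsilon, length.out = n)
  # enforce exact symmetry about 0.5 against seq() round-off
  p <- (p + rev(1 - p)) / 2
  h <- diff(p)
  w <- c(h[1] / 2, (h[-length(h)] + h[-1]) / 2, h[length(h)] / 2)
  structure(
    list(points = p, llr_points = p_to_llr(p), epsilon = epsilon, weights = w),
    class = "belief_grid"
  )
}

#' @export
print.belief_grid <- function(x, ...) {
  cat(sprintf(
    "belief_grid: %d points on [%g, %g]\n",
    length(x$points), x$points[1], x$points[length(x$points)]
  ))
  invisible(x)
}

#' Convert between state likelihood and log-likelihood ratio
#'
#' The state likelihood and the LLR are the two equivalent belief coordinates:
#' \eqn{p = 1 / (1 + e^{-y})} and \eqn{y = \ln(p / (1 - p))}.
#'
#' @param value Numeric vector of likelihoods or LLRs.
#' @param from Coordinate of `value`: `"p"` (likelihood, converted to LLR) or
#'   `"llr"` (converted to likelihood).
#' @return The converted vector.
#' @examples
#' convert_belief(0.75, from = "p")      # log(3)
#' convert_belief(0, from = "llr")       # 0.5
#' @export
convert_belief <- function(value, from = c("p", "llr")) {
  from <- match.arg(from)
  if (from == "p") p_to_llr(value) else llr_to_p(value)
}

#' @rdname convert_belief
#' @export
p_to_llr <- function(value) {
  if (any(value <= 0 | value >= 1)) stop("likelihood must lie strictly in (0, 1)")
  log(value) - log1p(-value)
}

#' @rdname convert_belief
#' @export
llr_to_p <- function(value) {
  if (any(!is.finite(value))) stop("LLR must be finite")
  1 / (1 + exp(-value))
}

#' Gaussian evidence model
#'
#' Observations in the continuous-context tasks are drawn from
#' \eqn{f_\pm(\xi) = N(\pm\mu, \sigma^2)}; in discrete time with step
#' `delta_t` each sample is \eqn{N(\pm\mu\,\delta t, \sigma^2 \delta t)}.
#' The evidence quality (scaled signal-to-noise ratio) is
#' \eqn{m = 2\mu^2/\sigma^2}, in units of 1/time.
#'
#' @param mu Drift magnitude \eqn{\mu \ge 0}.
#' @param sigma Observation noise \eqn{\sigma > 0}.
#' @param delta_t Observation interval (time units).
#' @return An object of class `evidence_model` with fields `mu`, `sigma`,
#'   `m`, `delta_t`.
#' @examples
#' evidence_model_from_snr(5)$mu^2  # 2.5 when sigma = 1
#' @export
evidence_model <- function(mu, sigma = 1, delta_t = 0.01) {
  if (sigma <= 0) stop("sigma must be positive")
  if (delta_t <= 0) stop("delta_t must be positive")
  if (mu < 0) stop("mu must be nonnegative")
  structure(
    list(mu = mu, sigma = sigma, m = 2 * mu^2 / sigma^2, delta_t = delta_t),
    class = "evidence_model"
  )
}

#' @rdname evidence_model
#' @param m Evidence quality \eqn{m = 2\mu^2/\sigma^2}; the implied drift is
#'   \eqn{\mu = \sigma\sqrt{m/2}}.
#' @export
evidence_model_from_snr <- function(m, sigma = 1, delta_t = 0.01) {
  if (m < 0) stop("evidence quality m must be nonnegative")
  evidence_model(mu = sigma * sqrt(m / 2), sigma = sigma, delta_t = delta_t)
}

#' One-observation log-likelihood-ratio update
#'
#' For Gaussian evidence the LLR update after observing `xi` is additive:
#' \eqn{y_n = y_{n-1} + 2\xi\mu/\sigma^2}, the log-ratio of the two Gaussian
#' observation densities.
#'
#' @param y_prev Previous LLR (numeric vector).
#' @param xi Observation(s), drawn from \eqn{N(\pm\mu\delta t, \sigma^2\delta t)}.
#' @param model An [evidence_model()].
#' @return Updated LLR.
#' @export
llr_update <- function(y_prev, xi, model) {
  stopifnot(inherits(model, "evidence_model"))
  y_prev + 2 * xi * model$mu / model$sigma^2
}

#' One-step likelihood transfer density
#'
#' The conditional density \eqn{f_p(p_{n+1} \mid p_n)} of the next-step state
#' likelihood given the current one, for Gaussian evidence.  It is the
#' two-component mixture obtained by marginalizing over the latent state
#' (weight \eqn{p_n} on the \eqn{s_+} branch and \eqn{1 - p_n} on the
#' \eqn{s_-} branch) and changing variables from the observation to the
#' likelihood through the monotone map
#' \eqn{\xi_{n+1} = \frac{\sigma^2}{2\mu}(y_{n+1} - y_n)}.
#'
#' @param p_next Destination likelihood(s) in (0, 1); vectorized.
#' @param p_curr Current likelihood (scalar) in (0, 1).
#' @param model An [evidence_model()] with `mu > 0`.
#' @return Density values (nonnegative), one per `p_next`.
#' @export
gaussian_transfer_density <- function(p_next, p_curr, model) {
  stopifnot(inherits(model, "evidence_model"))
  if (length(p_curr) != 1L) stop("p_curr must be scalar")
  if (p_curr <= 0 || p_curr >= 1 || any(p_next <= 0 | p_next >= 1)) {
    stop("likelihoods must lie strictly in (0, 1); clip to the grid first")
  }
  if (model$mu == 0) stop("transfer density is degenerate (a point mass) when mu = 0")
  mu <- model$mu; sigma <- model$sigma; dt <- model$delta_t
  # xi that produces the jump p_curr -> p_next, and the Jacobian d xi / d p'
  xi <- sigma^2 / (2 * mu) * (p_to_llr(p_next) - p_to_llr(p_curr))
  jac <- sigma^2 / (2 * mu * p_next * (1 - p_next))
  sd_xi <- sigma * sqrt(dt)
  jac * (p_curr * dnorm(xi, mean = mu * dt, sd = sd_xi) +
         (1 - p_curr) * dnorm(xi, mean = -mu * dt, sd = sd_xi))
}

#' Discretized likelihood transfer matrix
#'
#' Samples the one-step transfer density at the grid points, applies the
#' trapezoid quadrature weights of the grid, and renormalizes each row to sum
#' to one.  Row i is the discrete distribution of the next-step likelihood
#' given the current likelihood `grid$points[i]`; the expectation of the next
#' value function under the Bellman recursion is then a matrix-vector
#' product.  For uninformative evidence (`mu = 0`) the likelihood cannot
#' move and the identity matrix is returned.
#'
#' The mirror symmetry \eqn{f_p(1-p' \mid 1-p) = f_p(p' \mid p)} is enforced
#' exactly: rows for p > 0.5 are the reversal of their mirror rows.
#'
#' @param grid A [belief_grid()].
#' @param model An [evidence_model()].
#' @return A `transfer_matrix` object: the row-stochastic matrix with
#'   attributes `grid` and `model`.
#' @export
build_transfer_matrix <- function(grid, model) {
  stopifnot(inherits(grid, "belief_grid"), inherits(model, "evidence_model"))
  p <- grid$points
  n <- length(p)
  if (n < 3L) stop("degenerate grid: need at least 3 points")
  M <- matrix(0, n, n)
  if (model$mu == 0) {
    diag(M) <- 1
  } else {
    half <- (n + 1L) %/% 2L
    for (i in seq_len(half)) {
      row <- gaussian_transfer_density(p, p[i], model) * grid$weights
      M[i, ] <- row / sum(row)
    }
    # the middle row must be exactly palindromic for floating-point mirror
    # symmetry of the whole matrix
    M[half, ] <- (M[half, ] + rev(M[half, ])) / 2
    for (i in seq.int(half + 1L, n)) M[i, ] <- rev(M[n + 1L - i, ])
  }
  structure(M, class = c("transfer_matrix", "matrix"),
            grid = grid, model = model)
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat(sprintf("transfer_matrix: %d x %d (m = %g, delta_t = %g)\n",
              nrow(x), ncol(x), attr(x, "model")$m, attr(x, "model")$delta_t))
  invisible(x)
}

#' Simulate a noisy belief path
#'
#' Euler–Maruyama integration of the noisy Bayesian belief
#' \eqn{d\tilde y = \pm m\,dt + \sqrt{2m}\,dW_t + \sigma_y\,dW'_t},
#' where the drift sign follows the latent state, \eqn{\sqrt{2m}\,dW_t} is
#' the sampling noise inherent to the evidence stream, and \eqn{\sigma_y}
#' scales an independent sensory-noise Wiener process.
#'
#' @param state Latent state, +1 or -1 (sign of the drift).
#' @param model An [evidence_model()]; supplies `m` and `delta_t`.
#' @param sigma_y Sensory-noise strength (>= 0).
#' @param horizon Path length in time units (> 0).
#' @param seed Optional integer seed for reproducibility.
#' @return A data.frame with columns `t` and `y` (the path starts at y = 0).
#' @export
simulate_belief_path <- function(state, model, sigma_y = 0, horizon, seed = NULL) {
  stopifnot(inherits(model, "evidence_model"))
  if (!state %in% c(-1, 1)) stop("state must be +1 or -1")
  if (sigma_y < 0) stop("sigma_y must be nonnegative")
  if (horizon <= 0) stop("horizon must be positive")
  if (!is.null(seed)) set.seed(seed)
  dt <- model$delta_t
  nstep <- ceiling(horizon / dt)
  inc <- state * model$m * dt +
    sqrt(2 * model$m * dt) * rnorm(nstep) +
    sigma_y * sqrt(dt) * rnorm(nstep)
  data.frame(t = dt * (0:nstep), y = c(0, cumsum(inc)))
}

#' Export a transfer matrix or belief path as CSV
#'
#' @param x A `transfer_matrix` or the data.frame returned by
#'   [simulate_belief_path()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_belief_csv <- function(x, file) {
  if (inherits(x, "transfer_matrix")) {
    df <- as.data.frame(unclass(x))
    names(df) <- sprintf("p_%g", attr(x, "grid")$points)
    write.csv(cbind(p_from = attr(x, "grid")$points, df), file, row.names = FALSE)
  } else {
    write.csv(x, file, row.names = FALSE)
  }
  invisible(file)
}
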