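# Task-context schedules: piecewise-constant reward / cost / evidence-quality
# time courses plus the tokens-task and inferred-reward variants.

piecewise_spec <- function(breaks, values) {
  breaks <- as.numeric(breaks)
  values <- as.numeric(values)
  if (length(values) != length(breaks) + 1L) {
    stop("piecewise spec needs one more value than breakpoints")
  }
  if (is.unsorted(breaks, strictly = TRUE)) stop("breakpoints must be strictly increasing")
  list(breaks = breaks, values = values)
}

# right-continuous lookup: values[i] applies on [breaks[i-1], breaks[i])
piecewise_eval <- function(spec, t) {
  idx <- findInterval(t, spec$breaks, left.open = FALSE) + 1L
  spec$values[idx]
}

new_context_schedule <- function(kind, fields) {
  structure(c(list(kind = kind), fields), class = "context_schedule")
}

#' Shared settings for continuous-evidence dynamic-context tasks
#'
#' Bundles the task parameters that the single-change constructors share: the
#' evidence quality \eqn{m = 2\mu^2/\sigma^2}, incremental cost, punishment,
#' inter-trial interval, time discretization, and the analysis window.  The
#' solver horizon is extended to `t_final = 5 * window` so that backward
#' induction is insensitive to the artificial end time over the window where
#' decisions actually occur.
#'
#' @param m Evidence quality (1/time).
#' @param sigma Observation noise; the drift is \eqn{\mu = \sigma\sqrt{m/2}}.
#' @param cost Constant incremental evidence cost c.
#' @param reward_incorrect Punishment Ri for an incorrect choice.
#' @param iti Average inter-trial interval (time units).
#' @param delta_t Time step for observations and backward induction.
#' @param window Analysis window: thresholds are reported and trials are
#'   simulated on \[0, window\].
#' @return A list of shared settings consumed by the schedule constructors.
#' @export
base_context <- function(m = 5, sigma = 1, cost = 1, reward_incorrect = 0,
                         iti = 1, delta_t = 0.01, window = 1) {
  if (window <= 0 || delta_t <= 0) stop("window and delta_t must be positive")
  list(m = m, sigma = sigma, cost = cost, reward_incorrect = reward_incorrect,
       iti = iti, delta_t = delta_t, window = window, t_final = 5 * window)
}

continuous_context <- function(reward, mu, base, change_times = numeric(0)) {
  if (base$t_final <= 0) stop("t_final must be positive")
  new_context_schedule("continuous", list(
    reward = reward,
    reward_incorrect = base$reward_incorrect,
    cost = piecewise_spec(numeric(0), base$cost),
    mu = mu,
    sigma = base$sigma,
    iti = base$iti,
    delta_t = base$delta_t,
    window = base$window,
    t_final = base$t_final,
    change_times = change_times
  ))
}

#' Single-change reward schedule
#'
#' Builds the reward-change task: the correct-choice reward steps from `R1`
#' to `R2` at t = 0.5 (Heaviside, right-continuous, so Rc(0.5) = R2), with
#' constant evidence quality.  Punishment, cost, inter-trial interval and
#' discretization come from `base`.
#'
#' @param R1,R2 Pre- and post-change reward for a correct choice.
#' @param base Shared settings from [base_context()].
#' @param change_time Time of the reward switch.
#' @return A `context_schedule` of kind `"continuous"`.
#' @examples
#' ctx <- make_reward_change_schedule(3, 8)
#' context_reward(ctx, c(0.25, 0.75))  # 3 then 8
#' @export
make_reward_change_schedule <- function(R1, R2, base = base_context(),
                                        change_time = 0.5) {
  if (!is.finite(R1) || !is.finite(R2)) stop("rewards must be finite")
  if (R1 == R2) {
    return(continuous_context(piecewise_spec(numeric(0), R1),
                              piecewise_spec(numeric(0), base$sigma * sqrt(base$m / 2)),
                              base))
  }
  continuous_context(
    piecewise_spec(change_time, c(R1, R2)),
    piecewise_spec(numeric(0), base$sigma * sqrt(base$m / 2)),
    base, change_times = change_time
  )
}

#' Complementary reward pair with fixed total
#'
#' Helper for performance comparisons at matched average total reward: given
#' the pre-change reward, returns `c(R1, total - R1)`.
#'
#' @param R1 Pre-change reward.
#' @param total Fixed sum R1 + R2 (default 11).
#' @return Numeric length-2 vector `c(R1, R2)`.
#' @export
reward_pair_constrained <- function(R1, total = 11) c(R1 = R1, R2 = total - R1)

#' Single-change evidence-quality schedule
#'
#' Builds the SNR-change task: the drift steps from `mu1` to `mu2` at
#' t = 0.5, so the quality m(t) = 2 mu(t)^2 / sigma^2 steps accordingly.
#' Reward is constant (`Rc`).  The DP solver builds one transfer matrix per
#' quality piece and switches between them at the known change time.
#'
#' @param mu1,mu2 Pre- and post-change drift magnitudes (>= 0).
#' @param base Shared settings from [base_context()]; its `m` is ignored.
#' @param Rc Constant correct-choice reward.
#' @param change_time Time of the quality switch.
#' @return A `context_schedule` of kind `"continuous"`.
#' @export
make_snr_change_schedule <- function(mu1, mu2, base = base_context(), Rc = 5,
                                     change_time = 0.5) {
  if (mu1 < 0 || mu2 < 0) stop("drift magnitudes must be nonnegative")
  mu <- if (mu1 == mu2) piecewise_spec(numeric(0), mu1) else
    piecewise_spec(change_time, c(mu1, mu2))
  continuous_context(piecewise_spec(numeric(0), Rc), mu, base,
                     change_times = if (mu1 == mu2) numeric(0) else change_time)
}

#' Piecewise-constant multi-change schedule
#'
#' General constructor for environments with several reward or quality
#' changes within a trial.
#'
#' @param breakpoints Strictly increasing change times inside (0, t_final).
#' @param values One value per piece (`length(breakpoints) + 1`).
#' @param field `"reward"` or `"mu"`: which schedule varies.
#' @param base Shared settings from [base_context()].
#' @param Rc Constant reward used when `field = "mu"`.
#' @return A `context_schedule` of kind `"continuous"`.
#' @export
make_multi_change_schedule <- function(breakpoints, values,
                                       field = c("reward", "mu"),
                                       base = base_context(), Rc = 5) {
  field <- match.arg(field)
  if (length(values) != length(breakpoints) + 1L) {
    stop("need one value per piece: length(values) == length(breakpoints) + 1")
  }
  if (length(breakpoints) &&
      (min(breakpoints) <= 0 || max(breakpoints) >= base$t_final)) {
    stop("breakpoints must lie inside (0, t_final)")
  }
  spec <- piecewise_spec(breakpoints, values)
  const_mu <- piecewise_spec(numeric(0), base$sigma * sqrt(base$m / 2))
  if (field == "reward") {
    continuous_context(spec, const_mu, base, change_times = breakpoints)
  } else {
    if (any(values < 0)) stop("drift magnitudes must be nonnegative")
    continuous_context(piecewise_spec(numeric(0), Rc), spec, base,
                       change_times = breakpoints)
  }
}

#' Evaluate schedule fields over time
#'
#' Right-continuous lookups of the reward, cost, drift and inter-trial
#' interval schedules of a context.
#'
#' @param context A `context_schedule`.
#' @param t Time(s) in \[0, t_final\] (for the tokens task, in seconds, or an
#'   integer number of observed token movements times 0.2 s).
#' @return Numeric vector of field values at `t`.
#' @export
context_reward <- function(context, t) piecewise_eval(context$reward, t)

#' @rdname context_reward
#' @export
context_cost <- function(context, t) piecewise_eval(context$cost, t)

#' @rdname context_reward
#' @export
context_mu <- function(context, t) {
  if (context$kind != "continuous") stop("mu schedule applies to continuous contexts")
  piecewise_eval(context$mu, t)
}

#' @rdname context_reward
#' @export
context_iti <- function(context, t) {
  if (context$kind == "tokens") {
    n <- round(t / context$delta_t)
    if (any(n < 0 | n > context$n_tokens)) stop("token step outside 0..15")
    context$base_iti + (context$n_tokens - n) * context$anim_interval
  } else {
    rep_len(context$iti, length(t))
  }
}

#' @export
print.context_schedule <- function(x, ...) {
  cat(sprintf("context_schedule (%s): delta_t = %g, t_final = %g\n",
              x$kind, x$delta_t, x$t_final))
  if (length(x$change_times)) {
    cat("  change times:", paste(x$change_times, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tokens-task context
#'
#' The tokens task: 15 tokens jump from a center target to the upper or lower
#' target with probability 1/2, one every 200 ms; the subject predicts which
#' side ends with the majority.  After commitment at token movement n the
#' remaining 15 - n tokens finish their animation at an accelerated interval
#' (170 ms/token in the slow condition, 20 ms in the fast one), so the
#' effective inter-trial interval decreases with decision time — the task is
#' a multi-change reward task with commitment value modulated through
#' \eqn{\langle t_i \rangle}.
#'
#' @param speed `"slow"` or `"fast"` post-decision animation.
#' @param Rc Reward for a correct prediction.
#' @param cost Constant incremental evidence cost (per second).
#' @param Ri Punishment for an incorrect prediction (default -1).
#' @param base_iti Fixed component of the inter-trial interval in seconds,
#'   added to the remaining animation time.
#' @return A `context_schedule` of kind `"tokens"`.
#' @examples
#' ctx <- make_tokens_context("slow", Rc = 2, cost = 0.5)
#' context_iti(ctx, c(0, 3))  # 0.5 + 15*0.17, then 0.5
#' @export
make_tokens_context <- function(speed = c("slow", "fast"), Rc, cost, Ri = -1,
                                base_iti = 0.5) {
  speed <- match.arg(speed)
  anim <- if (speed == "slow") 0.17 else 0.02
  n_tokens <- 15L
  dt <- 0.2
  new_context_schedule("tokens", list(
    reward = piecewise_spec(numeric(0), Rc),
    reward_incorrect = Ri,
    cost = piecewise_spec(numeric(0), cost),
    speed = speed,
    anim_interval = anim,
    base_iti = base_iti,
    n_tokens = n_tokens,
    delta_t = dt,
    window = n_tokens * dt,
    t_final = n_tokens * dt,
    change_times = numeric(0)
  ))
}

#' Tokens-task state likelihood
#'
#' Probability that the upper target ends with the token majority given the
#' current counts: with C tokens still in the center and L already in the
#' lower target, the top side wins iff at most `7 - L` of the remaining
#' tokens fall to the bottom, i.e. the Binomial(C, 1/2) CDF at
#' `min(C, 7 - L)`.
#'
#' @param U,L,C Token counts in the upper, lower and center targets
#'   (vectorized; must satisfy U + L + C = 15).
#' @return Probability (in \[0, 1\]) that the top target wins.
#' @examples
#' tokens_likelihood(0, 0, 15)  # 0.5 by symmetry
#' tokens_likelihood(5, 3, 7)   # 99/128
#' @export
tokens_likelihood <- function(U, L, C) {
  k <- pmax(length(U), length(L), length(C))
  U <- rep_len(U, k); L <- rep_len(L, k); C <- rep_len(C, k)
  if (any(U < 0 | L < 0 | C < 0)) stop("token counts must be nonnegative")
  if (any(U + L + C != 15)) stop("unreachable state: U + L + C must equal 15")
  ifelse(7 - L < 0, 0, pbinom(pmin(C, 7 - L), C, 0.5))
}

#' Tokens-task one-step transfer
#'
#' From a state with C >= 1 center tokens the next token movement leads to
#' exactly two successors, each with probability 1/2: one token joins the
#' upper or the lower target.
#'
#' @param U,L,C Token counts of the current state (scalars, U + L + C = 15).
#' @return A data.frame with columns `U`, `L`, `C`, `prob` (two rows).
#' @export
tokens_transfer <- function(U, L, C) {
  if (length(U) != 1L || length(L) != 1L || length(C) != 1L) {
    stop("tokens_transfer takes a single state")
  }
  if (U + L + C != 15 || any(c(U, L, C) < 0)) stop("unreachable token state")
  if (C < 1) stop("terminal state: no center tokens left to move")
  U <- unname(U); L <- unname(L); C <- unname(C)
  data.frame(U = c(U + 1, U), L = c(L, L + 1), C = C - 1, prob = 0.5)
}

#' Two-state Markov reward process for the inferred reward-change task
#'
#' Reward alternates between `R_high` and `R_low` via a continuous-time
#' two-state Markov process with hazard rate `h`; the current state must be
#' inferred from an independent Gaussian evidence stream
#' \eqn{\eta \mid R_{H/L} \sim N(\pm\mu_R, \sigma_R^2)} with quality
#' \eqn{m_R = 2\mu_R^2/\sigma_R^2}.  The reward belief
#' \eqn{y_R = \ln[\Pr(R_H)/\Pr(R_L)]} follows the nonlinear diffusion
#' \eqn{dy_R = x(t) m_R\,dt - 2h\sinh(y_R)\,dt + \sqrt{2 m_R}\,dW}.
#'
#' @param R_high,R_low High and low reward values (`R_high >= R_low`).
#' @param hazard Transition rate h >= 0 (1/time).
#' @param mu_R,sigma_R Reward-evidence distribution parameters.
#' @return An object of class `reward_process_model`.
#' @export
reward_process_model <- function(R_high, R_low, hazard, mu_R, sigma_R = 1) {
  if (R_high < R_low) stop("R_high must be >= R_low")
  if (hazard < 0) stop("hazard must be nonnegative")
  if (sigma_R <= 0) stop("sigma_R must be positive")
  structure(
    list(R_high = R_high, R_low = R_low, hazard = hazard,
         mu_R = mu_R, sigma_R = sigma_R, m_R = 2 * mu_R^2 / sigma_R^2),
    class = "reward_process_model"
  )
}

#' Inferred reward-change context
#'
#' Context whose DP state is two-dimensional: the choice belief p and the
#' reward belief q = Pr(R(t) = R_high).  Commitment values use the expected
#' reward `R_high * q + R_low * (1 - q)` (punishment fixed at 0); the
#' q-dynamics follow one Euler step of the sinh-nonlinearity diffusion per
#' timestep.
#'
#' @param proc A [reward_process_model()].
#' @param base Shared settings from [base_context()].
#' @return A `context_schedule` of kind `"inferred"`.
#' @export
make_inferred_reward_context <- function(proc, base = base_context()) {
  stopifnot(inherits(proc, "reward_process_model"))
  new_context_schedule("inferred", list(
    proc = proc,
    reward = piecewise_spec(numeric(0), NA_real_),  # reward is belief-dependent
    reward_incorrect = 0,
    cost = piecewise_spec(numeric(0), base$cost),
    mu = piecewise_spec(numeric(0), base$sigma * sqrt(base$m / 2)),
    sigma = base$sigma,
    iti = base$iti,
    delta_t = base$delta_t,
    window = base$window,
    t_final = base$t_final,
    change_times = numeric(0)
  ))
}

#' Export a schedule as CSV
#'
#' Writes the time courses (t, Rc, mu, cost, iti) of a context on its native
#' time grid.
#'
#' @param context A `context_schedule`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_schedule_csv <- function(context, file) {
  t <- seq(0, context$t_final, by = context$delta_t)
  df <- data.frame(
    t = t,
    Rc = if (context$kind == "inferred") NA_real_ else context_reward(context, t),
    mu = if (context$kind == "continuous") context_mu(context, t) else NA_real_,
    cost = context_cost(context, t),
    iti = context_iti(context, t)
  )
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}
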