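# Forward simulators for the three observer models (noisy Bayesian,
# constant-threshold, urgency-gating), reward-rate estimation and
# grid-search tuning of the heuristic models.

#' Observer model parameter sets
#'
#' Constructors for the parameter bundles of the three decision models:
#' noisy Bayesian (`nb_params`: reward `Rc`, evidence cost `cost`, plus
#' noise), constant threshold (`const_params`: LLR threshold `theta0` plus
#' noise) and urgency gating (`ugm_params`: threshold scale `theta0`, gain
#' `gain`, filter time constant `tau`, plus noise).  All models share the
#' sensory-noise strength `sigma_y` (diffusive corruption of the belief) and
#' the motor-noise SD `sigma_mn` (Gaussian response-time jitter).
#'
#' @param Rc Reward for a correct choice (noisy Bayesian).
#' @param cost Incremental evidence cost (noisy Bayesian).
#' @param theta0 Threshold (constant model) or threshold scale (urgency).
#' @param gain Urgency gain a: the bound collapses as `theta0 / (a t)`.
#' @param tau Low-pass filter time constant (urgency).
#' @param sigma_y Sensory-noise strength (>= 0).
#' @param sigma_mn Motor-noise SD in time units (>= 0).
#' @return A `model_params` object with subclass `nb_params`,
#'   `const_params` or `ugm_params`.
#' @export
nb_params <- function(Rc, cost, sigma_y = 0, sigma_mn = 0) {
  check_noise(sigma_y, sigma_mn)
  structure(list(Rc = Rc, cost = cost, sigma_y = sigma_y, sigma_mn = sigma_mn),
            class = c("nb_params", "model_params"))
}

#' @rdname nb_params
#' @export
const_params <- function(theta0, sigma_y = 0, sigma_mn = 0) {
  if (theta0 <= 0) stop("theta0 must be positive")
  check_noise(sigma_y, sigma_mn)
  structure(list(theta0 = theta0, sigma_y = sigma_y, sigma_mn = sigma_mn),
            class = c("const_params", "model_params"))
}

#' @rdname nb_params
#' @param ugm_alt If `TRUE`, use the alternative bound form
#'   `theta0 / (1 + a t)` (finite at t = 0).
#' @export
ugm_params <- function(theta0, gain, tau, sigma_y = 0, sigma_mn = 0,
                       ugm_alt = FALSE) {
  if (theta0 <= 0 || gain <= 0 || tau <= 0) {
    stop("theta0, gain and tau must be positive")
  }
  check_noise(sigma_y, sigma_mn)
  structure(list(theta0 = theta0, gain = gain, tau = tau, sigma_y = sigma_y,
                 sigma_mn = sigma_mn, ugm_alt = isTRUE(ugm_alt)),
            class = c("ugm_params", "model_params"))
}

check_noise <- function(sigma_y, sigma_mn) {
  if (sigma_y < 0) stop("sigma_y must be nonnegative")
  if (sigma_mn < 0) stop("sigma_mn must be nonnegative")
  invisible(TRUE)
}

model_kind <- function(params) {
  if (inherits(params, "nb_params")) "nb"
  else if (inherits(params, "const_params")) "const"
  else if (inherits(params, "ugm_params")) "ugm"
  else stop("not a model_params object")
}

#' Shared evidence streams for model comparison
#'
#' Pre-draws the latent states and the two standard-normal increment
#' matrices (evidence sampling noise and sensory noise) used by the trial
#' simulator.  Replaying the same streams through different models ensures
#' that performance differences come only from their threshold behavior.
#'
#' @param context A continuous `context_schedule`.
#' @param n_trials Number of trials.
#' @param seed Optional integer seed.
#' @return A list with `states`, increment matrices `z_sample` and
#'   `z_sensory` (steps x trials), and the step times `t`.
#' @export
make_evidence_streams <- function(context, n_trials, seed = NULL) {
  stopifnot(context$kind == "continuous")
  if (!is.null(seed)) set.seed(seed)
  dt <- context$delta_t
  K <- round(context$window / dt)
  list(states = sample(c(-1, 1), n_trials, replace = TRUE),
       z_sample = matrix(rnorm(K * n_trials), K, n_trials),
       z_sensory = matrix(rnorm(K * n_trials), K, n_trials),
       t = dt * (0:K))
}

threshold_vectors <- function(params, context, thresholds, t) {
  kind <- model_kind(params)
  if (kind == "nb") {
    if (is.null(thresholds)) {
      stop("the noisy Bayesian model needs a ThresholdTrace solved for its (Rc, cost)")
    }
    if (nrow(thresholds) < length(t)) {
      stop("threshold trace shorter than the simulation window: context mismatch")
    }
    idx <- match(round(t, 10), round(thresholds$t, 10))
    if (anyNA(idx)) stop("threshold trace times do not align with the context timestep")
    thresholds$theta_llr_upper[idx]
  } else if (kind == "const") {
    rep(params$theta0, length(t))
  } else {
    ifelse(t > 0,
           if (params$ugm_alt) params$theta0 / (1 + params$gain * t)
           else params$theta0 / (params$gain * t),
           Inf)
  }
}

#' Simulate decision trials in a continuous-evidence context
#'
#' Integrates the noisy belief (Euler-Maruyama) on the analysis window and
#' records the first crossing of the model's (possibly time-varying) bounds.
#' The noisy Bayesian and constant-threshold models compare the noisy LLR
#' against their bounds; the urgency-gating model low-pass filters the state
#' likelihood and compares the filter output against a collapsing bound.
#' Trials that never cross are forced to the sign of the belief at the end
#' of the window (exact zeros break ties by a fair coin).  Observed response
#' times pass through the Gaussian motor filter.
#'
#' @param params A `model_params` object.
#' @param context A continuous `context_schedule`.
#' @param thresholds A `threshold_trace` (required for `nb_params`; solved
#'   at the same `Rc` and `cost`).
#' @param n_trials Number of trials (ignored if `streams` given).
#' @param seed Optional integer seed.
#' @param streams Optional [make_evidence_streams()] result for
#'   common-random-number comparisons.
#' @return A data.frame (one row per trial): `trial`, `state`, `choice`,
#'   `rt_raw`, `rt_observed`, `correct`, `reward`.
#' @export
simulate_trials <- function(params, context, thresholds = NULL,
                            n_trials = 1000L, seed = NULL, streams = NULL) {
  stopifnot(inherits(params, "model_params"), context$kind == "continuous")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(streams)) streams <- make_evidence_streams(context, n_trials)
  n <- length(streams$states)
  t <- streams$t
  K <- length(t) - 1L
  dt <- context$delta_t
  kind <- model_kind(params)
  thr_up <- threshold_vectors(params, context, thresholds, t)
  m_t <- 2 * context_mu(context, t)^2 / context$sigma^2

  y <- numeric(n)
  E <- numeric(n)
  active <- rep(TRUE, n)
  rt <- rep(t[K + 1L], n)
  ch <- integer(n)
  for (k in 0:K) {
    bel <- if (kind == "ugm") E else y
    up <- thr_up[k + 1L]
    if (is.finite(up)) {
      hit <- active & (bel >= up | bel <= -up)
      if (any(hit)) {
        s <- sign(bel[hit])
        zero <- s == 0
        if (any(zero)) s[zero] <- ifelse(runif(sum(zero)) < 0.5, 1, -1)
        ch[hit] <- s
        rt[hit] <- t[k + 1L]
        active[hit] <- FALSE
      }
    }
    if (k == K) break
    drift <- streams$states * m_t[k + 1L] * dt
    samp <- sqrt(2 * m_t[k + 1L] * dt) * streams$z_sample[k + 1L, ]
    if (kind == "ugm") {
      y <- y + drift + samp
      E <- E + dt / params$tau * (-E + 1 / (1 + exp(-y)) - 0.5) +
        params$sigma_y * sqrt(dt) * streams$z_sensory[k + 1L, ]
    } else {
      y <- y + drift + samp +
        params$sigma_y * sqrt(dt) * streams$z_sensory[k + 1L, ]
    }
  }
  if (any(active)) {  # forced choice at the end of the window
    bel <- if (kind == "ugm") E else y
    s <- sign(bel[active])
    zero <- s == 0
    if (any(zero)) s[zero] <- ifelse(runif(sum(zero)) < 0.5, 1, -1)
    ch[active] <- s
  }
  rt_obs <- apply_motor_filter(rt, params$sigma_mn, window = c(0, t[K + 1L]))
  correct <- ch == streams$states
  reward <- ifelse(correct, context_reward(context, rt_obs),
                   context$reward_incorrect)
  data.frame(trial = seq_len(n), state = streams$states, choice = ch,
             rt_raw = rt, rt_observed = rt_obs, correct = correct,
             reward = reward)
}

#' @rdname simulate_trials
#' @export
simulate_nb_trial <- function(params, context, thresholds, seed = NULL) {
  simulate_trials(params, context, thresholds, n_trials = 1L, seed = seed)
}

#' @rdname simulate_trials
#' @export
simulate_const_trial <- function(params, context, seed = NULL) {
  simulate_trials(params, context, n_trials = 1L, seed = seed)
}

#' @rdname simulate_trials
#' @export
simulate_ugm_trial <- function(params, context, seed = NULL) {
  simulate_trials(params, context, n_trials = 1L, seed = seed)
}

#' Gaussian response-time filter
#'
#' Observed response times are the model's crossing times corrupted by
#' zero-mean Gaussian jitter of SD `sigma_mn`, redrawn until they fall
#' inside the simulation window (rejection resampling).  Represents both
#' early responses (attentional lapses) and late ones (motor delays).
#'
#' @param rt_raw Vector of model crossing times (inside `window`).
#' @param sigma_mn Motor-noise SD (>= 0).
#' @param window Length-2 numeric: the admissible time interval.
#' @param seed Optional integer seed.
#' @return Filtered response times, same length as `rt_raw`.
#' @export
apply_motor_filter <- function(rt_raw, sigma_mn, window, seed = NULL) {
  if (sigma_mn < 0) stop("sigma_mn must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  if (sigma_mn == 0) return(rt_raw)
  if (any(rt_raw < window[1] - 1e-12 | rt_raw > window[2] + 1e-12)) {
    stop("rt_raw outside the admissible window")
  }
  out <- rt_raw + sigma_mn * rnorm(length(rt_raw))
  bad <- out < window[1] | out > window[2]
  while (any(bad)) {
    out[bad] <- rt_raw[bad] + sigma_mn * rnorm(sum(bad))
    bad <- out < window[1] | out > window[2]
  }
  out
}

#' Estimate the trial-averaged reward rate from simulated trials
#'
#' Computes \eqn{\hat\rho = (\bar R - \bar{c\,T_d}) / (\bar T_d + \bar t_i)}
#' with a delta-method standard error for the ratio of means.
#'
#' @param trials A trial data.frame from [simulate_trials()].
#' @param context The `context_schedule` the trials were simulated in.
#' @return A list with `rho`, `se` and `n`.
#' @export
estimate_reward_rate <- function(trials, context) {
  n <- nrow(trials)
  if (is.null(n) || n < 2L) stop("need at least two trials")
  td <- trials$rt_observed
  cost <- context_cost(context, td) * td
  ti <- context_iti(context, td)
  num <- trials$reward - cost
  den <- td + ti
  rho <- mean(num) / mean(den)
  v <- stats::var(num) - 2 * rho * stats::cov(num, den) + rho^2 * stats::var(den)
  list(rho = rho, se = sqrt(max(v, 0) / n) / mean(den), n = n)
}

#' Tune a heuristic model by grid search
#'
#' Approximates the best achievable reward rate of the constant-threshold or
#' urgency-gating model by evaluating every candidate parameter set on the
#' same evidence streams (common random numbers) and returning the argmax.
#'
#' @param model_kind `"const"` or `"ugm"`.
#' @param context A continuous `context_schedule`.
#' @param grid A data.frame of candidate parameters (`theta0` for const;
#'   `theta0`, `gain`, `tau` for ugm).
#' @param n_trials Trials per candidate.
#' @param seed Integer seed for the shared streams.
#' @return A list with `params` (best `model_params`), `rho`, `se`, and the
#'   full `table` of candidate results.
#' @export
tune_heuristic <- function(model_kind = c("const", "ugm"), context, grid,
                           n_trials = 4000L, seed = 1L) {
  model_kind <- match.arg(model_kind)
  grid <- as.data.frame(grid)
  if (!nrow(grid)) stop("empty tuning grid")
  streams <- make_evidence_streams(context, n_trials, seed = seed)
  rhos <- ses <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    params <- if (model_kind == "const") {
      const_params(grid$theta0[i])
    } else {
      ugm_params(grid$theta0[i], grid$gain[i], grid$tau[i])
    }
    tr <- simulate_trials(params, context, streams = streams)
    est <- estimate_reward_rate(tr, context)
    rhos[i] <- est$rho
    ses[i] <- est$se
  }
  best <- which.max(rhos)
  params <- if (model_kind == "const") const_params(grid$theta0[best]) else
    ugm_params(grid$theta0[best], grid$gain[best], grid$tau[best])
  list(params = params, rho = rhos[best], se = ses[best],
       table = cbind(grid, rho = rhos, se = ses))
}

#' Combined noise strength of a synthetic subject
#'
#' The ratio \eqn{(\sigma_y + \sigma_{mn}) / (\bar\sigma_y + \bar\sigma_{mn})}
#' mapping a subject's sensory and motor noise onto \[0, 1\], where the
#' denominators are the maximum strengths considered
#' (\eqn{\bar\sigma_y = 5}, \eqn{\bar\sigma_{mn} = 0.25}).
#'
#' @param sigma_y Sensory-noise strength in \[0, sigma_y_max\].
#' @param sigma_mn Motor-noise SD in \[0, sigma_mn_max\].
#' @param sigma_y_max,sigma_mn_max Maximum considered strengths.
#' @return Noise strength in \[0, 1\].
#' @export
noise_strength <- function(sigma_y, sigma_mn, sigma_y_max = 5,
                           sigma_mn_max = 0.25) {
  if (any(sigma_y < 0 | sigma_y > sigma_y_max)) {
    stop("sigma_y outside [0, ", sigma_y_max, "]")
  }
  if (any(sigma_mn < 0 | sigma_mn > sigma_mn_max)) {
    stop("sigma_mn outside [0, ", sigma_mn_max, "]")
  }
  (sigma_y + sigma_mn) / (sigma_y_max + sigma_mn_max)
}
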