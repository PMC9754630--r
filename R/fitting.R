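# Tokens-task model fitting: Monte-Carlo response-time-distribution
# likelihood, Metropolis MCMC with bounded flat priors, and the model
# selection metrics (AICc, trial-wise RMSE, KL divergence).

.tokens_cache <- new.env(parent = emptyenv())

tokens_pmat <- function() {
  if (is.null(.tokens_cache$pmat)) {
    p <- tokens_state_likelihoods(15L)
    p[is.na(p)] <- 0.5  # unreachable entries, never read
    .tokens_cache$pmat <- p
  }
  .tokens_cache$pmat
}

tokens_iti_vector <- function(speed, base_iti = 0.5) {
  anim <- if (speed == "slow") 0.17 else 0.02
  base_iti + (15:0) * anim
}

#' Reward-rate-optimal tokens-task thresholds
#'
#' Solves the tokens-task backward induction and reward-rate co-optimization
#' for a given reward and cost (compiled kernel; equivalent to
#' [solve_reward_rate()] on a tokens context, used in the inner loop of
#' model fitting).
#'
#' @param Rc Reward for a correct prediction.
#' @param cost Incremental evidence cost (per second).
#' @param Ri Punishment (default -1).
#' @param speed `"slow"` or `"fast"`.
#' @param base_iti Fixed inter-trial delay (seconds).
#' @param rho_init Optional warm start for the reward-rate root.
#' @param tol Root tolerance on the start value.
#' @return A list with `rho`, `thr_p`, `thr_llr` (length 16, `Inf` where the
#'   observer never responds) and the action matrix.
#' @export
solve_tokens_thresholds <- function(Rc, cost, Ri = -1,
                                    speed = c("slow", "fast"),
                                    base_iti = 0.5, rho_init = NA_real_,
                                    tol = 1e-8) {
  speed <- match.arg(speed)
  cpp_tokens_solve(tokens_pmat(), tokens_iti_vector(speed, base_iti),
                   Rc, cost, Ri, 0.2, rho_init, tol * max(1, abs(Rc)))
}

#' Simulate tokens-task trials from an observer model
#'
#' Runs the discrete-time model (time step = one token movement, 200 ms) on
#' given or freshly drawn token sequences: the belief is the exact
#' token-state LLR plus accumulated sensory noise (the urgency model
#' low-pass filters the state likelihood instead), bound crossing triggers
#' the response, step 15 forces a choice, and the Gaussian motor filter
#' jitters the reported response time before snapping it to the 16 bins.
#'
#' @param params A `model_params` object ([nb_params()], [const_params()],
#'   [ugm_params()]).
#' @param speed `"slow"` or `"fast"` (sets the commitment-value schedule the
#'   noisy Bayesian thresholds are solved under).
#' @param sequences Matrix of token moves (+1 up / -1 down, trials x 15);
#'   drawn fresh if `NULL`.
#' @param n_trials Number of trials when `sequences` is `NULL`.
#' @param seed Optional integer seed.
#' @param thresholds Optional precomputed [solve_tokens_thresholds()] result
#'   (noisy Bayesian only).
#' @return A data.frame with `trial`, `rt_bin` (0..15), `rt_raw` (seconds),
#'   `choice`, `state` (final majority), `correct`.
#' @export
simulate_tokens_trials <- function(params, speed = c("slow", "fast"),
                                   sequences = NULL, n_trials = 1000L,
                                   seed = NULL, thresholds = NULL) {
  speed <- match.arg(speed)
  stopifnot(inherits(params, "model_params"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sequences)) sequences <- generate_token_sequences(n_trials)
  kind <- model_kind(params)
  thr_llr <- rep(0, 16)
  theta0 <- gain <- tau <- 0
  if (kind == "nb") {
    if (is.null(thresholds)) {
      thresholds <- solve_tokens_thresholds(params$Rc, params$cost,
                                            speed = speed)
    }
    thr_llr <- thresholds$thr_llr
  } else if (kind == "const") {
    theta0 <- params$theta0
  } else {
    theta0 <- params$theta0
    gain <- params$gain
    tau <- params$tau
  }
  res <- cpp_sim_tokens(switch(kind, nb = 1L, const = 2L, ugm = 3L),
                        sequences, tokens_pmat(), thr_llr, theta0, gain, tau,
                        params$sigma_y, params$sigma_mn,
                        as.integer(isTRUE(params$ugm_alt)))
  data.frame(trial = seq_len(nrow(sequences)), rt_bin = res$rt_bin,
             rt_raw = res$rt_raw, choice = res$choice, state = res$state,
             correct = res$choice == res$state)
}

#' Model response-time distribution over the 16 bins
#'
#' Monte-Carlo estimate of the probability of responding after i token
#' movements (i = 0..15): simulate trials on random token sequences,
#' histogram the binned response times, floor at 1e-6 and renormalize (the
#' floor keeps log-likelihoods finite).
#'
#' @inheritParams simulate_tokens_trials
#' @param n_sim Number of simulated trials (>= 1000).
#' @return Numeric vector of length 16 summing to one.
#' @export
predict_rt_distribution <- function(params, speed = c("slow", "fast"),
                                    n_sim = 1000L, seed = NULL,
                                    sequences = NULL) {
  if (n_sim < 1000L && is.null(sequences)) {
    stop("n_sim must be at least 1000 for a usable distribution estimate")
  }
  trials <- simulate_tokens_trials(params, speed, sequences = sequences,
                                   n_trials = n_sim, seed = seed)
  h <- tabulate(trials$rt_bin + 1L, nbins = 16L)
  p <- pmax(h / sum(h), 1e-6)
  p / sum(p)
}

#' Log-likelihood of a subject dataset under a model
#'
#' The objective is the marginal response-time distribution: the
#' log-likelihood is the sum over trials of the log model probability of the
#' observed response bin.
#'
#' @param params A `model_params` object.
#' @param data A `subject_dataset` (see [generate_synthetic_subject()]).
#' @param n_sim Simulated trials for the distribution estimate.
#' @param seed Optional seed (fix it across evaluations to tame Monte-Carlo
#'   jitter when comparing parameter sets).
#' @return Scalar log-likelihood (finite thanks to the distribution floor).
#' @export
log_likelihood <- function(params, data, n_sim = 1000L, seed = NULL) {
  stopifnot(inherits(data, "subject_dataset"))
  if (!length(data$rt_bin)) stop("empty dataset")
  rtm <- predict_rt_distribution(params, data$speed, n_sim = n_sim,
                                 seed = seed)
  sum(log(rtm[data$rt_bin + 1L]))
}

# Bounded flat priors wide enough to contain all threshold-motif regimes;
# default proposal SDs pre-tuned on a synthetic tuning cohort toward the
# 20-25% acceptance sweet spot of the Monte-Carlo likelihood surface.
model_par_info <- function(model_kind) {
  switch(model_kind,
    nb = list(names = c("Rc", "cost", "sigma_y", "sigma_mn"),
              lower = c(1e-3, 0, 0, 0), upper = c(50, 10, 5, 0.25),
              prop = c(0.5, 0.12, 0.08, 0.005)),
    const = list(names = c("theta0", "sigma_y", "sigma_mn"),
                 lower = c(1e-3, 0, 0), upper = c(10, 5, 0.25),
                 prop = c(0.1, 0.08, 0.005)),
    ugm = list(names = c("theta0", "gain", "sigma_y", "tau", "sigma_mn"),
               lower = c(1e-3, 1e-3, 0, 0.01, 0),
               upper = c(10, 10, 5, 2, 0.25),
               prop = c(0.1, 0.1, 0.08, 0.025, 0.005)),
    stop("unknown model kind")
  )
}

# coarse lattice over the prior box; the best cell starts the chain so the
# random walk does not have to cross the whole (often ridge-shaped) surface
scan_chain_start <- function(model_kind, ll_fun) {
  grids <- switch(model_kind,
    nb = expand.grid(Rc = c(1, 2, 4, 8, 16, 32), cost = c(0.1, 0.3, 1, 3, 8),
                     sigma_y = c(0.5, 1.5, 3), sigma_mn = c(0.05, 0.15)),
    const = expand.grid(theta0 = c(0.25, 0.5, 1, 1.5, 2.5, 4, 6, 9),
                        sigma_y = c(0.5, 1.5, 3), sigma_mn = c(0.05, 0.15)),
    ugm = expand.grid(theta0 = c(0.1, 0.25, 0.6, 1.5, 4),
                      gain = c(0.25, 0.75, 2, 5),
                      sigma_y = c(0.05, 0.2, 0.8, 2.5), tau = c(0.1, 0.4, 1),
                      sigma_mn = c(0.05, 0.15))
  )
  lls <- apply(grids, 1, function(row) ll_fun(as.numeric(row)))
  x <- as.numeric(grids[which.max(lls), ])
  refine_start(x, ll_fun, model_par_info(model_kind))
}

# cheap coordinate-wise refinement of the scan optimum: for each parameter
# in turn, try a geometric fan of candidates (clipped to the prior box) and
# keep the best; two sweeps are enough to escape coarse-lattice artifacts
refine_start <- function(x, ll_fun, info, n_sweeps = 2L) {
  best_ll <- ll_fun(x)
  fan <- c(1 / 3, 1 / 2, 3 / 4, 1.33, 2, 3)
  for (sweep in seq_len(n_sweeps)) {
    for (j in seq_along(x)) {
      cand <- unique(pmin(pmax(x[j] * fan, info$lower[j]), info$upper[j]))
      for (v in cand) {
        xx <- x
        xx[j] <- v
        ll <- ll_fun(xx)
        if (ll > best_ll) {
          best_ll <- ll
          x <- xx
        }
      }
    }
  }
  x
}

params_from_vector <- function(model_kind, x) {
  switch(model_kind,
    nb = nb_params(x[1], x[2], x[3], x[4]),
    const = const_params(x[1], x[2], x[3]),
    ugm = ugm_params(x[1], x[2], sigma_y = x[3], tau = x[4], sigma_mn = x[5])
  )
}

#' Metropolis MCMC over model parameters
#'
#' Random-walk Metropolis with a diagonal Gaussian proposal and bounded flat
#' priors (out-of-bounds proposals are rejected).  The Monte-Carlo
#' likelihood uses one fixed simulation seed for the whole chain (common
#' random numbers), so the pseudo-likelihood surface is deterministic
#' within a chain.  The first 10% of samples are treated as burn-in by the
#' summaries.
#'
#' @param data A `subject_dataset`.
#' @param model_kind `"nb"`, `"const"` or `"ugm"`.
#' @param chain_length Number of posterior samples.
#' @param proposal_sd Optional named vector of proposal SDs (defaults to 5%
#'   of each prior range).
#' @param seed Integer seed (drives both the chain and the fixed simulation
#'   stream).
#' @param n_sim Simulated trials per likelihood evaluation.
#' @param init Optional named start vector (defaults to mid-prior).
#' @return A `posterior_samples` object: `samples` matrix, `log_like`
#'   vector, `acceptance_rate`, `map` (named vector), `map_log_like`,
#'   `model_kind`, `burn`.
#' @export
mcmc_sample <- function(data, model_kind = c("nb", "const", "ugm"),
                        chain_length = 10000L, proposal_sd = NULL,
                        seed = 1L, n_sim = 1000L, init = NULL) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(data, "subject_dataset"))
  info <- model_par_info(model_kind)
  k <- length(info$names)
  if (is.null(proposal_sd)) proposal_sd <- info$prop
  proposal_sd <- rep_len(proposal_sd, k)
  set.seed(seed)
  sim_seed <- sample.int(.Machine$integer.max, 1L)
  sequences <- generate_token_sequences(n_sim)
  counts <- tabulate(data$rt_bin + 1L, nbins = 16L)
  ll_fun <- function(x) {
    rng <- get(".Random.seed", envir = globalenv())
    set.seed(sim_seed)
    rtm <- predict_rt_distribution(params_from_vector(model_kind, x),
                                   data$speed, sequences = sequences)
    assign(".Random.seed", rng, envir = globalenv())
    sum(counts * log(rtm))
  }
  x <- if (is.null(init)) {
    scan_chain_start(model_kind, ll_fun)  # coarse lattice scan
  } else unname(init[info$names])
  ll <- ll_fun(x)
  samples <- matrix(NA_real_, chain_length, k,
                    dimnames = list(NULL, info$names))
  lls <- numeric(chain_length)
  n_acc <- 0L
  n_rej_run <- 0L
  for (i in seq_len(chain_length)) {
    prop <- x + proposal_sd * rnorm(k)
    if (all(prop >= info$lower & prop <= info$upper)) {
      ll_prop <- ll_fun(prop)
      if (log(runif(1)) < ll_prop - ll) {
        x <- prop
        ll <- ll_prop
        n_acc <- n_acc + 1L
        n_rej_run <- 0L
      } else n_rej_run <- n_rej_run + 1L
    } else n_rej_run <- n_rej_run + 1L
    if (n_acc == 0L && i >= 500L) {
      stop("no accepted proposal in the first 500 steps: proposal scale likely too large")
    }
    samples[i, ] <- x
    lls[i] <- ll
  }
  burn <- ceiling(chain_length / 10)
  post <- seq.int(burn + 1L, chain_length)
  # The frozen common-random-number surface makes the raw argmax sample a
  # noisy maximizer of the true likelihood: re-score the best distinct
  # post-burn-in candidates on fresh validation streams and keep the winner.
  cand <- unique(samples[post, , drop = FALSE])
  cand_ll <- lls[post][!duplicated(samples[post, , drop = FALSE])]
  ord <- order(cand_ll, decreasing = TRUE)[seq_len(min(20L, nrow(cand)))]
  cand <- cand[ord, , drop = FALSE]
  val_seeds <- sample.int(.Machine$integer.max, 3L)
  n_val <- 4L * n_sim  # larger shared streams: candidate comparisons are
  val_ll <- rep(0, nrow(cand))  # common-random-number differences
  for (vs in val_seeds) {
    set.seed(vs)
    val_seqs <- generate_token_sequences(n_val)
    for (j in seq_len(nrow(cand))) {
      set.seed(vs + 1L)
      rtm <- predict_rt_distribution(
        params_from_vector(model_kind, cand[j, ]), data$speed,
        sequences = val_seqs)
      val_ll[j] <- val_ll[j] + sum(counts * log(rtm))
    }
  }
  imax <- which.max(val_ll)
  structure(
    list(samples = samples, log_like = lls,
         acceptance_rate = n_acc / chain_length,
         map = cand[imax, ], map_log_like = val_ll[imax] / 3,
         model_kind = model_kind, burn = burn, seed = seed,
         candidates = list(params = cand, chain_log_like = cand_ll[ord],
                           validation_log_like = val_ll)),
    class = "posterior_samples"
  )
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("posterior_samples (%s): %d samples, acceptance %.2f\n",
              x$model_kind, nrow(x$samples), x$acceptance_rate))
  cat("MAP:", paste(sprintf("%s=%.3g", names(x$map), x$map), collapse = ", "),
      "\n")
  invisible(x)
}

#' Corrected Akaike information criterion
#'
#' \eqn{AICc = 2k - 2\ln\hat L + (2k^2 + 2k) / (n - k - 1)}; converges to
#' AIC for large n.
#'
#' @param log_like_hat Maximized log-likelihood.
#' @param k Number of model parameters.
#' @param n Number of observations (must exceed k + 1).
#' @return Scalar AICc.
#' @examples
#' aicc(-50, k = 3, n = 100)  # 106.25
#' @export
aicc <- function(log_like_hat, k, n) {
  if (n <= k + 1) stop("AICc needs n > k + 1")
  2 * k - 2 * log_like_hat + (2 * k^2 + 2 * k) / (n - k - 1)
}

#' Kullback-Leibler divergence between response-time distributions
#'
#' \eqn{KL = \sum_{i=0}^{15} RTD(i)\,\ln(RTD(i)/RTM(i))} with the
#' convention \eqn{0 \ln 0 = 0}; the model distribution should be floored
#' (see [predict_rt_distribution()]) so the sum is finite.
#'
#' @param rtd Data distribution (length 16, sums to 1).
#' @param rtm Model distribution (length 16, sums to 1, strictly positive).
#' @return Nonnegative scalar.
#' @export
kl_divergence <- function(rtd, rtm) {
  if (length(rtd) != 16L || length(rtm) != 16L) {
    stop("both distributions must have 16 bins")
  }
  if (any(rtd < 0) || any(rtm <= 0)) stop("invalid distribution values")
  pos <- rtd > 0
  sum(rtd[pos] * log(rtd[pos] / rtm[pos]))
}

#' Empirical response-time distribution of a dataset
#'
#' @param data A `subject_dataset`.
#' @return Length-16 probability vector over response bins 0..15.
#' @export
empirical_rt_distribution <- function(data) {
  stopifnot(inherits(data, "subject_dataset"))
  h <- tabulate(data$rt_bin + 1L, nbins = 16L)
  h / sum(h)
}

#' Trial-by-trial response-time RMSE
#'
#' For each trial, the predicted response time is the mean over `n_rep`
#' noisy replays of the model on that trial's token sequence; the score is
#' the root-mean-squared error (in seconds) between predicted and observed
#' response times across trials.
#'
#' @param params A `model_params` object (typically the MAP fit).
#' @param data A `subject_dataset`.
#' @param n_rep Replays per trial.
#' @param seed Optional seed.
#' @return Scalar RMSE in seconds.
#' @export
trial_rmse <- function(params, data, n_rep = 20L, seed = NULL) {
  stopifnot(inherits(data, "subject_dataset"))
  if (n_rep < 1L) stop("n_rep must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  thresholds <- if (inherits(params, "nb_params")) {
    solve_tokens_thresholds(params$Rc, params$cost, speed = data$speed)
  }
  n <- nrow(data$sequences)
  pred <- numeric(n)
  seqs_rep <- data$sequences[rep(seq_len(n), each = n_rep), , drop = FALSE]
  tr <- simulate_tokens_trials(params, data$speed, sequences = seqs_rep,
                               thresholds = thresholds)
  pred <- tapply(tr$rt_bin * 0.2, rep(seq_len(n), each = n_rep), mean)
  sqrt(mean((as.numeric(pred) - data$rt_bin * 0.2)^2))
}

#' Fit one model to a subject dataset
#'
#' Convenience wrapper: runs [mcmc_sample()], evaluates the model-selection
#' metrics at the MAP parameters, and returns a `fit_result`.
#'
#' @inheritParams mcmc_sample
#' @param n_rep Replays per trial for the RMSE metric.
#' @return A `fit_result`: `map_params`, `log_like_hat`, `k`, `n`, `aicc`,
#'   `rmse`, `kl`, `posterior`.
#' @export
fit_tokens_model <- function(data, model_kind = c("nb", "const", "ugm"),
                             chain_length = 10000L, seed = 1L,
                             n_sim = 1000L, n_rep = 20L,
                             proposal_sd = NULL) {
  model_kind <- match.arg(model_kind)
  if (is.null(proposal_sd)) proposal_sd <- model_par_info(model_kind)$prop
  post <- NULL
  for (attempt in 1:3) {
    post <- tryCatch(
      mcmc_sample(data, model_kind, chain_length = chain_length,
                  seed = seed + attempt - 1L, n_sim = n_sim,
                  proposal_sd = proposal_sd),
      error = function(e) {
        if (!grepl("proposal scale", conditionMessage(e))) stop(e)
        NULL
      })
    if (!is.null(post)) break
    proposal_sd <- proposal_sd / 2  # stalled chain: shrink the random walk
  }
  if (is.null(post)) stop("MCMC failed to move even after shrinking the proposal")
  map_params <- params_from_vector(model_kind, post$map)
  k <- length(post$map)
  n <- length(data$rt_bin)
  rtm <- predict_rt_distribution(map_params, data$speed, n_sim = n_sim,
                                 seed = seed + 1L)
  structure(
    list(map_params = map_params, map = post$map,
         log_like_hat = post$map_log_like, k = k, n = n,
         aicc = aicc(post$map_log_like, k, n),
         rmse = trial_rmse(map_params, data, n_rep = n_rep, seed = seed + 2L),
         kl = kl_divergence(empirical_rt_distribution(data), rtm),
         acceptance_rate = post$acceptance_rate,
         posterior = post, model_kind = model_kind),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result (%s): lnL = %.2f, AICc = %.2f, RMSE = %.3f s, KL = %.4f\n",
              x$model_kind, x$log_like_hat, x$aicc, x$rmse, x$kl))
  invisible(x)
}

#' Select the winning model for a subject
#'
#' Argmin of the chosen criterion across fitted models; near-ties (within
#' 1e-9) are reported rather than broken silently.
#'
#' @param fits Named list of `fit_result` objects (one per model).
#' @param criterion `"aicc"` or `"rmse"`.
#' @return A list with `winner` (model name), `values`, and `ties`
#'   (character vector of tied models, length > 1 if tied).
#' @export
select_model <- function(fits, criterion = c("aicc", "rmse")) {
  criterion <- match.arg(criterion)
  if (!length(fits) || !all(vapply(fits, inherits, TRUE, "fit_result"))) {
    stop("fits must be a named list of fit_result objects")
  }
  if (is.null(names(fits)) || any(names(fits) == "")) {
    stop("fits must be named by model")
  }
  vals <- vapply(fits, function(f) f[[criterion]], numeric(1))
  best <- min(vals)
  ties <- names(vals)[vals <= best + 1e-9]
  list(winner = names(vals)[which.min(vals)], values = vals, ties = ties)
}
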