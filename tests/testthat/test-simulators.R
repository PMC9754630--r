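test_that("constant-threshold accuracy matches the absorption oracle", {
  # the continuous-time absorption probability is 1/(1 + e^-theta); the
  # discrete walk overshoots the bound, so the oracle is an independent
  # random-walk simulation at the same step size
  base <- quick_base(window = 3)  # long window: almost every trial absorbs
  ctx <- make_reward_change_schedule(5, 5, base)
  theta <- 1.1
  n <- 2e4
  trials <- simulate_trials(const_params(theta), ctx, n_trials = n, seed = 5)
  absorbed <- trials$rt_raw < 3
  acc <- mean(trials$correct[absorbed])
  # oracle: plain cumulative-sum walk, state +1 w.l.o.g. by symmetry
  set.seed(105)
  dt <- base$delta_t
  m <- base$m
  correct_oracle <- rep(NA, n)
  y <- rep(0, n)
  alive <- rep(TRUE, n)
  for (k in seq_len(round(3 / dt))) {
    y[alive] <- y[alive] + m * dt + sqrt(2 * m * dt) * rnorm(sum(alive))
    hit <- alive & abs(y) >= theta
    correct_oracle[hit] <- y[hit] > 0
    alive[alive] <- !hit[alive]
  }
  acc_oracle <- mean(correct_oracle, na.rm = TRUE)
  se <- sqrt(acc_oracle * (1 - acc_oracle) * (1 / n + 1 / n))
  expect_gt(mean(absorbed), 0.99)
  expect_lt(abs(acc - acc_oracle), 3 * se)
  # and both exceed the continuous-time bound thanks to overshoot
  expect_gt(acc, 1 / (1 + exp(-theta)))
})

test_that("simulation is deterministic under a fixed seed", {
  ctx <- make_reward_change_schedule(3, 8, quick_base())
  t1 <- simulate_trials(const_params(1, 0.5, 0.05), ctx, n_trials = 50,
                        seed = 42)
  t2 <- simulate_trials(const_params(1, 0.5, 0.05), ctx, n_trials = 50,
                        seed = 42)
  expect_identical(t1, t2)
  one <- simulate_const_trial(const_params(1), ctx, seed = 9)
  expect_equal(nrow(one), 1)
})

test_that("shared streams make model differences threshold-only", {
  ctx <- make_reward_change_schedule(3, 8, quick_base())
  streams <- make_evidence_streams(ctx, 500, seed = 7)
  # a constant-threshold trace fed to the NB simulator reproduces the
  # constant-threshold model exactly on the same streams
  theta0 <- 1.3
  t_axis <- seq(0, ctx$t_final, by = ctx$delta_t)
  trace <- make_trace(t_axis, rep(llr_to_p(theta0), length(t_axis)))
  trace$theta_llr_upper <- rep(theta0, length(t_axis))
  nb_like <- simulate_trials(nb_params(3, 1), ctx, thresholds = trace,
                             streams = streams)
  const <- simulate_trials(const_params(theta0), ctx, streams = streams)
  expect_identical(nb_like[c("choice", "rt_raw")], const[c("choice", "rt_raw")])
})

test_that("noisy Bayesian respects infinite early thresholds", {
  ctx <- make_reward_change_schedule(1, 8, quick_base())
  sol <- quick_solve(ctx)
  tr <- extract_thresholds(sol)
  trials <- simulate_trials(nb_params(1, 1, sigma_y = 3), ctx,
                            thresholds = tr, n_trials = 2000, seed = 11)
  expect_true(all(trials$rt_raw >= 0.5))  # no responses while waiting is forced
  # constant threshold responds early in the same low-reward epoch
  ct <- simulate_trials(const_params(1, sigma_y = 3), ctx, n_trials = 2000,
                        seed = 11)
  expect_gt(mean(ct$rt_raw < 0.5), 0.2)
})

test_that("urgency model stays put with uninformative input", {
  base <- quick_base()
  base$m <- 0
  ctx <- make_snr_change_schedule(0, 0, base)
  trials <- simulate_trials(ugm_params(0.3, 1, 0.2), ctx, n_trials = 200,
                            seed = 3)
  expect_true(all(trials$rt_raw == ctx$window))  # never crosses, forced choice
})

test_that("motor filter is an in-window Gaussian jitter", {
  expect_identical(apply_motor_filter(c(0.2, 0.7), 0, c(0, 1)), c(0.2, 0.7))
  set.seed(13)
  out <- apply_motor_filter(rep(0.5, 2e4), 0.05, c(0, 1))
  expect_true(all(out >= 0 & out <= 1))
  expect_lt(abs(sd(out) - 0.05), 0.002)  # window wide relative to sigma
  expect_lt(abs(mean(out) - 0.5), 3 * 0.05 / sqrt(2e4))
  expect_error(apply_motor_filter(0.5, -1, c(0, 1)), "nonnegative")
  expect_error(apply_motor_filter(2, 0.1, c(0, 1)), "window")
})

test_that("reward-rate estimator reduces to arithmetic on degenerate trials", {
  ctx <- make_reward_change_schedule(5, 5, quick_base())
  trials <- data.frame(rt_observed = rep(0.4, 50), reward = rep(5, 50),
                       correct = TRUE)
  est <- estimate_reward_rate(trials, ctx)
  expect_equal(est$rho, (5 - 1 * 0.4) / (0.4 + 1))
  expect_equal(est$se, 0)
  zero <- data.frame(rt_observed = rep(0.4, 10), reward = 0, correct = FALSE)
  base0 <- quick_base()
  base0$cost <- 0
  ctx0 <- make_reward_change_schedule(0, 0, base0)
  expect_equal(estimate_reward_rate(zero, ctx0)$rho, 0)
  expect_error(estimate_reward_rate(trials[1, , drop = FALSE], ctx),
               "at least two")
})

test_that("grid-search tuning is monotone in the grid", {
  ctx <- make_reward_change_schedule(3, 8, quick_base())
  narrow <- tune_heuristic("const", ctx, data.frame(theta0 = c(0.5, 1)),
                           n_trials = 800, seed = 2)
  wide <- tune_heuristic("const", ctx,
                         data.frame(theta0 = c(0.5, 1, 1.5, 2)),
                         n_trials = 800, seed = 2)
  expect_gte(wide$rho, narrow$rho)
  expect_error(tune_heuristic("const", ctx, data.frame()), "empty")
})

test_that("noise strength is the normalized sum of noise scales", {
  expect_equal(noise_strength(0, 0), 0)
  expect_equal(noise_strength(5, 0.25), 1)
  expect_equal(noise_strength(2.5, 0.125), 0.5)
  expect_error(noise_strength(6, 0.1), "outside")
  expect_error(noise_strength(1, 0.3), "outside")
})
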