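test_that("AICc follows its closed form and limits", {
  expect_equal(aicc(-50, k = 3, n = 100), 106.25)
  expect_equal(aicc(-50, k = 3, n = 1e9), 2 * 3 - 2 * (-50),
               tolerance = 1e-6)  # converges to plain AIC
  expect_gt(aicc(-50, 5, 100), aicc(-50, 4, 100))
  expect_error(aicc(-50, 4, 5), "n > k")
})

test_that("KL divergence satisfies its identities", {
  u <- rep(1 / 16, 16)
  expect_equal(kl_divergence(u, u), 0)
  rtd <- c(1, rep(0, 15))
  rtm <- c(0.5, 0.5, rep(1e-9, 14))
  rtm <- rtm / sum(rtm)
  expect_equal(kl_divergence(rtd, rtm), log(2), tolerance = 1e-6)
  set.seed(17)
  for (i in 1:200) {
    a <- rexp(16); a <- a / sum(a)
    b <- rexp(16) + 1e-6; b <- b / sum(b)
    expect_gte(kl_divergence(a, b), 0)
  }
  expect_error(kl_divergence(u[1:8], u), "16 bins")
})

test_that("predicted RT distribution is a proper floored histogram", {
  p <- predict_rt_distribution(const_params(1.2, 1, 0.05), "slow",
                               n_sim = 1000, seed = 3)
  expect_length(p, 16)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_true(all(p > 0))
  # an unreachable threshold forces every response to the last bin
  p_inf <- predict_rt_distribution(const_params(25), "slow", n_sim = 1000,
                                   seed = 3)
  expect_equal(which.max(p_inf), 16)
  expect_gt(p_inf[16], 0.999)
  expect_error(predict_rt_distribution(const_params(1), "slow", n_sim = 10),
               "at least 1000")
})

test_that("log-likelihood is additive and prefers modal data", {
  params <- const_params(1.5, 0.8, 0.05)
  subj <- generate_synthetic_subject(params, "slow", n_trials = 100,
                                     seed = 5)
  ll1 <- log_likelihood(params, subj, seed = 7)
  doubled <- subject_dataset(rbind(subj$sequences, subj$sequences),
                             c(subj$rt_bin, subj$rt_bin), subj$speed)
  expect_equal(log_likelihood(params, doubled, seed = 7), 2 * ll1)
  rtm <- predict_rt_distribution(params, "slow", n_sim = 2000, seed = 7)
  modal <- subject_dataset(subj$sequences[1, , drop = FALSE],
                           which.max(rtm) - 1L, "slow")
  worst <- subject_dataset(subj$sequences[1, , drop = FALSE],
                           which.min(rtm) - 1L, "slow")
  expect_gt(log_likelihood(params, modal, seed = 7),
            log_likelihood(params, worst, seed = 7))
  # per-trial log-likelihood of self-generated data approaches -entropy
  big <- generate_synthetic_subject(params, "slow", n_trials = 4000,
                                    seed = 8)
  ll <- log_likelihood(params, big, n_sim = 4000, seed = 9) / 4000
  entropy <- -sum(rtm * log(rtm))
  expect_lt(abs(ll + entropy), 0.1)
})

test_that("more simulation reduces likelihood-estimate noise", {
  params <- const_params(1.5, 0.8, 0.05)
  subj <- generate_synthetic_subject(params, "slow", n_trials = 200,
                                     seed = 67)
  ll_sd <- function(n_sim) {
    sd(vapply(1:8, function(s) {
      log_likelihood(params, subj, n_sim = n_sim, seed = 500 + s)
    }, numeric(1)))
  }
  expect_lt(ll_sd(4000), ll_sd(1000))
})

test_that("MCMC chains are reproducible and move", {
  subj <- generate_synthetic_subject(const_params(1.5, 0.8, 0.05), "slow",
                                     n_trials = 150, seed = 19)
  p1 <- mcmc_sample(subj, "const", chain_length = 150, seed = 23)
  p2 <- mcmc_sample(subj, "const", chain_length = 150, seed = 23)
  expect_identical(p1$samples, p2$samples)
  expect_gt(p1$acceptance_rate, 0)
  expect_true(all(p1$samples[, "theta0"] > 0 & p1$samples[, "theta0"] <= 10))
  expect_equal(p1$burn, 15)
})

test_that("posterior credible intervals cover the generating reward and cost", {
  gen <- nb_params(4, 1, sigma_y = 1.2, sigma_mn = 0.06)
  subj <- generate_synthetic_subject(gen, "slow", n_trials = 1000, seed = 29)
  post <- mcmc_sample(subj, "nb", chain_length = 1200, seed = 31)
  keep <- post$samples[-seq_len(post$burn), , drop = FALSE]
  for (par in c("Rc", "cost")) {
    ci <- quantile(keep[, par], c(0.05, 0.95))
    expect_lte(ci[1], gen[[par]])
    expect_gte(ci[2], gen[[par]])
  }
})

test_that("trial RMSE vanishes for a deterministic self-fit", {
  params <- const_params(1.5)  # no sensory or motor noise
  subj <- generate_synthetic_subject(params, "slow", n_trials = 80,
                                     seed = 37)
  expect_equal(trial_rmse(params, subj, n_rep = 3, seed = 1), 0)
  # permutation invariance
  perm <- sample(length(subj$rt_bin))
  shuffled <- subject_dataset(subj$sequences[perm, ], subj$rt_bin[perm],
                              subj$speed)
  noisy <- const_params(1.5, 0.5, 0.04)
  expect_lt(abs(trial_rmse(noisy, subj, n_rep = 80, seed = 2) -
                  trial_rmse(noisy, shuffled, n_rep = 80, seed = 2)), 0.05)
})

test_that("model selection takes the argmin and reports ties", {
  f <- function(kind, a, r) structure(
    list(aicc = a, rmse = r, model_kind = kind), class = "fit_result")
  fits <- list(nb = f("nb", 100, 0.5), const = f("const", 102, 0.4),
               ugm = f("ugm", 101, 0.6))
  expect_equal(select_model(fits, "aicc")$winner, "nb")
  expect_equal(select_model(fits, "rmse")$winner, "const")
  expect_equal(select_model(rev(fits), "aicc")$winner, "nb")
  tied <- list(a = f("nb", 100, 1), b = f("const", 100 + 1e-12, 1))
  expect_length(select_model(tied, "aicc")$ties, 2)
  expect_error(select_model(list(f("nb", 1, 1)), "aicc"), "named")
})
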