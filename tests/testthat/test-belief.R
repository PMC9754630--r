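test_that("belief grid is symmetric, increasing and clipped", {
  g <- belief_grid(101, epsilon = 1e-4)
  expect_length(g$points, 101)
  expect_true(all(diff(g$points) > 0))
  expect_equal(g$points, rev(1 - g$points))
  expect_equal(min(g$points), 1e-4)
  expect_equal(max(g$points), 1 - 1e-4)
  expect_equal(g$llr_points, log(g$points / (1 - g$points)))
  expect_error(belief_grid(2), "at least 3")
  expect_error(belief_grid(100), "odd")
})

test_that("likelihood/LLR conversion is exact and monotone", {
  expect_equal(convert_belief(0, from = "llr"), 0.5)
  expect_equal(convert_belief(0.75, from = "p"), log(3))
  p <- seq(1e-6, 1 - 1e-6, length.out = 57)
  expect_equal(llr_to_p(p_to_llr(p)), p, tolerance = 1e-12)
  expect_true(all(diff(p_to_llr(p)) > 0))
  expect_gt(p_to_llr(1 - 1e-12), 20)  # unbounded growth toward p = 1
  expect_error(p_to_llr(1), "strictly")
  expect_error(p_to_llr(0), "strictly")
  expect_error(llr_to_p(Inf), "finite")
})

test_that("LLR update matches the batch joint-likelihood oracle", {
  model <- evidence_model(mu = 1.2, sigma = 0.8, delta_t = 0.05)
  set.seed(11)
  xi <- rnorm(40, mean = model$mu * model$delta_t,
              sd = model$sigma * sqrt(model$delta_t))
  y_seq <- 0
  for (x in xi) y_seq <- llr_update(y_seq, x, model)
  sd_xi <- model$sigma * sqrt(model$delta_t)
  y_batch <- sum(dnorm(xi, model$mu * model$delta_t, sd_xi, log = TRUE)) -
    sum(dnorm(xi, -model$mu * model$delta_t, sd_xi, log = TRUE))
  expect_equal(y_seq, y_batch, tolerance = 1e-10)
  # uninformative evidence and symmetric-zero observations leave y unchanged
  expect_equal(llr_update(0.7, 0.3, evidence_model(0, 1, 0.05)), 0.7)
  expect_equal(llr_update(0.7, 0, model), 0.7)
})

test_that("transfer density normalizes, mirrors, and matches Monte Carlo", {
  model <- evidence_model_from_snr(5, delta_t = 0.01)
  pgrid <- seq(1e-5, 1 - 1e-5, length.out = 4001)
  dens <- gaussian_transfer_density(pgrid, 0.3, model)
  expect_true(all(dens >= 0))
  mass <- sum(dens) * diff(pgrid[1:2])
  expect_equal(mass, 1, tolerance = 1e-3)
  # exact mirror symmetry
  expect_equal(gaussian_transfer_density(1 - pgrid, 0.7, model), dens)
  # Monte-Carlo one-step oracle from p = 0.5
  set.seed(21)
  n <- 1e5
  p0 <- 0.5
  dens <- gaussian_transfer_density(pgrid, p0, model)
  state_plus <- runif(n) < p0
  xi <- rnorm(n, mean = ifelse(state_plus, 1, -1) * model$mu * model$delta_t,
              sd = model$sigma * sqrt(model$delta_t))
  p1 <- llr_to_p(llr_update(p_to_llr(p0), xi, model))
  cdf_dens <- cumsum(dens) * diff(pgrid[1:2])
  cdf_at <- approx(pgrid, cdf_dens, xout = sort(p1))$y
  ks <- max(abs(cdf_at - seq_len(n) / n))
  expect_lt(ks, 0.01)
  expect_error(gaussian_transfer_density(0.5, 1, model), "strictly")
})

test_that("transfer matrix rows are stochastic, symmetric and martingale", {
  g <- belief_grid(201)
  M <- build_transfer_matrix(g, evidence_model_from_snr(5, delta_t = 0.01))
  expect_equal(unname(rowSums(M)), rep(1, 201), tolerance = 1e-6)
  # exact mirror symmetry: weights(i -> j) = weights(mirror(i) -> mirror(j))
  bare <- function(x) matrix(as.numeric(x), nrow(x))
  expect_identical(bare(M)[201:1, 201:1], bare(M))
  mean_next <- as.vector(unclass(M) %*% g$points)
  interior <- g$points > 0.05 & g$points < 0.95
  expect_lt(max(abs(mean_next - g$points)[interior]), 2e-3)
  # uninformative evidence cannot move the likelihood
  M0 <- build_transfer_matrix(g, evidence_model(0, 1, 0.01))
  expect_identical(bare(M0), diag(201))
  expect_error(build_transfer_matrix(belief_grid(3), evidence_model(1, 1, 0.01)),
               NA)
})

test_that("belief path simulator matches the SDE moments", {
  model <- evidence_model_from_snr(4, delta_t = 0.01)
  expect_equal(simulate_belief_path(1, evidence_model(0, 1, 0.01), 0, 1,
                                    seed = 1)$y, rep(0, 101))
  n <- 5000
  horizon <- 1
  set.seed(31)
  ends <- replicate(n, {
    inc <- model$m * model$delta_t +
      sqrt(2 * model$m * model$delta_t) * rnorm(100)
    sum(inc)
  })
  # against the simulator itself under a different seed stream
  ends_sim <- vapply(seq_len(n), function(i) {
    p <- simulate_belief_path(1, model, sigma_y = 0, horizon = horizon)
    p$y[nrow(p)]
  }, numeric(1))
  se <- sqrt(2 * model$m * horizon / n)
  expect_lt(abs(mean(ends_sim) - model$m * horizon), 3 * se)
  sigma_y <- 1.5
  ends2 <- vapply(seq_len(n), function(i) {
    p <- simulate_belief_path(1, model, sigma_y = sigma_y, horizon = horizon)
    p$y[nrow(p)]
  }, numeric(1))
  v_theory <- (2 * model$m + sigma_y^2) * horizon
  se_var <- v_theory * sqrt(2 / (n - 1))
  expect_lt(abs(var(ends2) - v_theory), 3 * se_var)
  expect_error(simulate_belief_path(1, model, sigma_y = -1, horizon = 1),
               "nonnegative")
  expect_error(simulate_belief_path(2, model, 0, 1), "\\+1 or -1")
  # reproducibility under a fixed seed
  p1 <- simulate_belief_path(-1, model, 0.5, 0.5, seed = 99)
  p2 <- simulate_belief_path(-1, model, 0.5, 0.5, seed = 99)
  expect_identical(p1, p2)
})
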