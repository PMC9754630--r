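test_that("terminal value is the better commitment, penalized", {
  g <- quick_grid(51)
  ctx <- make_reward_change_schedule(5, 5, quick_base())
  v <- terminal_value(g, ctx, rho = 0)
  expect_equal(v[(51 + 1) / 2], 2.5)  # p = 0.5, Rc = 5, Ri = 0
  expect_equal(v, rev(v))             # p <-> 1 - p symmetry
  v1 <- terminal_value(g, ctx, rho = 1.2)
  expect_equal(max(v1), 5 * max(g$points) - 1.2, tolerance = 1e-10)
  expect_equal(v - v1, rep(1.2, 51))
})

test_that("huge cost collapses thresholds; equal rewards force commitment", {
  base <- quick_base()
  base$cost <- 500
  ctx <- make_reward_change_schedule(5, 5, base)
  sol <- quick_solve(ctx, quick_grid(101))
  tr <- extract_thresholds(sol)
  expect_true(all(tr$theta_p_upper == 0.5))
  # Rc = Ri: commitment value independent of belief, waiting only pays costs
  base2 <- quick_base()
  base2$reward_incorrect <- 4
  ctx2 <- make_reward_change_schedule(4, 4, base2)
  sol2 <- quick_solve(ctx2, quick_grid(101))
  expect_true(all(sol2$action != 3L))
  expect_equal(max(abs(sol2$value - (4 - 1 * sol2$rho))), 0, tolerance = 1e-8)
})

test_that("reward-rate root satisfies the consistency condition", {
  ctx <- make_reward_change_schedule(3, 8, quick_base())
  sol <- quick_solve(ctx)
  expect_lt(abs(sol$v0), 1e-6 * 8)
  expect_equal(sol$value[, 1][(201 + 1) / 2], sol$v0)
  # g(rho) decreases in rho
  g1 <- backward_induction(ctx, sol$rho - 0.5, quick_grid(), full = FALSE)$v0
  g2 <- backward_induction(ctx, sol$rho + 0.5, quick_grid(), full = FALSE)$v0
  expect_gt(g1, 0)
  expect_lt(g2, 0)
  # raising both rewards raises the optimal reward rate
  sol_hi <- quick_solve(make_reward_change_schedule(5, 10, quick_base()))
  expect_gt(sol_hi$rho, sol$rho)
})

test_that("value and threshold symmetry hold for symmetric tasks", {
  sol <- quick_solve(make_reward_change_schedule(6, 2, quick_base()))
  expect_equal(sol$value, sol$value[nrow(sol$value):1, ])
  tr <- extract_thresholds(sol)
  fin <- is.finite(tr$theta_p_upper)
  expect_equal(tr$theta_p_lower[fin], 1 - tr$theta_p_upper[fin])
  expect_true(all(tr$theta_p_upper[fin] >= 0.5))
  expect_true(all(tr$theta_p_lower[fin] <= 0.5))
  expect_equal(tr$theta_llr_lower[fin], -tr$theta_llr_upper[fin],
               tolerance = 1e-9)
})

test_that("extreme reward switches produce the expected threshold epochs", {
  g <- quick_grid()
  # very low pre-change reward: wait out the low-reward epoch entirely
  lo_hi <- extract_thresholds(quick_solve(make_reward_change_schedule(
    1, 8, quick_base()), g))
  w <- lo_hi[lo_hi$t < 0.5, ]
  expect_true(all(!is.finite(w$theta_p_upper)))
  after <- lo_hi[lo_hi$t >= 0.5 & lo_hi$t <= 1, ]
  expect_true(all(is.finite(after$theta_p_upper)))
  # very high pre-change reward: thresholds reach 0.5 just before the drop
  hi_lo <- extract_thresholds(quick_solve(make_reward_change_schedule(
    8, 1, quick_base()), g))
  just_before <- hi_lo$theta_p_upper[hi_lo$t >= 0.4 & hi_lo$t <= 0.5]
  expect_lte(min(just_before) - 0.5, attr(hi_lo, "grid_step"))
})

test_that("static-task thresholds are horizon-insensitive on the window", {
  g <- quick_grid()
  sol1 <- quick_solve(make_reward_change_schedule(5, 5, quick_base()), g)
  base2 <- quick_base(window = 2)  # doubles t_final to 10
  sol2 <- quick_solve(make_reward_change_schedule(5, 5, base2), g)
  tr1 <- extract_thresholds(sol1)
  tr2 <- extract_thresholds(sol2)
  w <- tr1$t <= 1
  idx2 <- match(round(tr1$t[w], 10), round(tr2$t, 10))
  diffs <- abs(tr1$theta_p_upper[w] - tr2$theta_p_upper[idx2])
  expect_lte(max(diffs), attr(tr1, "grid_step") + 1e-12)
  # and the static thresholds are constant over the analysis window
  th <- tr1$theta_p_upper[w]
  expect_lte(max(th) - min(th), attr(tr1, "grid_step") + 1e-12)
})

test_that("tokens solver agrees with the compiled kernel and is consistent", {
  ctx <- make_tokens_context("slow", Rc = 2, cost = 0.5)
  solR <- solve_reward_rate(ctx)
  solC <- solve_tokens_thresholds(2, 0.5, speed = "slow")
  expect_equal(solR$rho, solC$rho, tolerance = 1e-9)
  expect_lt(abs(solR$v0), 1e-6 * 2)
  trR <- extract_thresholds(solR)
  expect_equal(trR$theta_p_upper, solC$thr_p)
  # forced terminal commitment: no waiting at step 15
  expect_true(all(solR$action[16, 1:16] != 3L, na.rm = TRUE))
})
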