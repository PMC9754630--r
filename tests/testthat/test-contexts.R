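test_that("reward-change schedule follows the right-continuous Heaviside", {
  ctx <- make_reward_change_schedule(3, 8)
  expect_equal(context_reward(ctx, c(0, 0.25, 0.499, 0.5, 0.75, 5)),
               c(3, 3, 3, 8, 8, 8))
  expect_equal(ctx$t_final, 5)
  expect_equal(unname(reward_pair_constrained(3)), c(3, 8))
  expect_equal(unname(reward_pair_constrained(7)["R2"]), 4)
  # zero jump collapses to a static schedule
  static <- make_reward_change_schedule(4, 4)
  expect_length(static$reward$breaks, 0)
  expect_equal(context_reward(static, c(0.1, 0.9)), c(4, 4))
})

test_that("SNR-change schedule steps the evidence quality", {
  ctx <- make_snr_change_schedule(1, 2)
  expect_equal(context_mu(ctx, c(0.49, 0.5)), c(1, 2))
  m_t <- 2 * context_mu(ctx, c(0.2, 0.8))^2 / ctx$sigma^2
  expect_equal(m_t, c(2, 8))
  expect_equal(context_reward(ctx, 0.7), 5)
  # equal drifts reuse a single transfer matrix
  same <- make_snr_change_schedule(1.5, 1.5)
  tr <- context_transfer_matrices(same, belief_grid(51))
  expect_length(tr$mats, 1)
  two <- context_transfer_matrices(ctx, belief_grid(51))
  expect_length(two$mats, 2)
  expect_error(make_snr_change_schedule(-1, 2), "nonnegative")
})

test_that("multi-change schedules cover the horizon and match single-change", {
  base <- quick_base()
  single <- make_reward_change_schedule(2, 6, base)
  multi <- make_multi_change_schedule(0.5, c(2, 6), "reward", base)
  t <- seq(0, base$t_final, by = 0.1)
  expect_equal(context_reward(multi, t), context_reward(single, t))
  none <- make_multi_change_schedule(numeric(0), 4, "reward", base)
  expect_equal(context_reward(none, t), rep(4, length(t)))
  three <- make_multi_change_schedule(c(0.3, 0.6, 0.9), c(1, 5, 2, 7),
                                      "reward", base)
  expect_equal(context_reward(three, c(0.29, 0.3, 0.61, 0.95)), c(1, 5, 2, 7))
  expect_error(make_multi_change_schedule(c(0.3, 0.2), c(1, 2, 3), "reward",
                                          base), "increasing")
  expect_error(make_multi_change_schedule(0.5, c(1, 2, 3), "reward", base),
               "length")
})

test_that("tokens likelihood equals the combinatorial oracle on all states", {
  states <- all_token_states()
  expect_equal(nrow(states), 136)
  got <- tokens_likelihood(states[, "U"], states[, "L"], states[, "C"])
  oracle <- vapply(seq_len(nrow(states)), function(i) {
    unname(tokens_likelihood_oracle(states[i, "U"], states[i, "L"],
                                    states[i, "C"]))
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-14)
  # direct enumeration of all remaining-token assignments for a small case
  enum <- expand.grid(rep(list(c(0, 1)), 7))  # 1 = token falls to the bottom
  top_wins <- rowSums(enum) + 3 <= 7
  expect_equal(tokens_likelihood(5, 3, 7), mean(top_wins))
  expect_equal(tokens_likelihood(5, 3, 7), 99 / 128)
  expect_equal(tokens_likelihood(0, 0, 15), 0.5)
  expect_equal(tokens_likelihood(0, 8, 7), 0)
  expect_equal(tokens_likelihood(8, 0, 7), 1)
  expect_error(tokens_likelihood(5, 5, 7), "unreachable")
})

test_that("tokens transfer is a fair split and the likelihood a martingale", {
  tr <- tokens_transfer(0, 0, 15)
  expect_equal(tr$U, c(1, 0))
  expect_equal(tr$L, c(0, 1))
  expect_equal(tr$prob, c(0.5, 0.5))
  states <- all_token_states()
  for (i in seq_len(nrow(states))) {
    s <- states[i, ]
    if (s["C"] < 1) next
    tr <- tokens_transfer(s["U"], s["L"], s["C"])
    expected <- sum(tr$prob * tokens_likelihood(tr$U, tr$L, tr$C))
    expect_equal(expected, tokens_likelihood(s["U"], s["L"], s["C"]))
  }
  expect_error(tokens_transfer(8, 7, 0), "terminal")
  # 15-step forward propagation from the start state stays at 1/2
  probs <- c(1)
  states_n <- matrix(c(0, 0, 15), 1)
  for (step in 1:15) {
    nxt <- list()
    for (j in seq_len(nrow(states_n))) {
      tr <- tokens_transfer(states_n[j, 1], states_n[j, 2], states_n[j, 3])
      nxt[[j]] <- cbind(as.matrix(tr[, 1:3]), probs[j] * tr$prob)
    }
    nxt <- do.call(rbind, nxt)
    key <- paste(nxt[, 1], nxt[, 2])
    agg <- rowsum(nxt[, 4], key)
    uk <- do.call(rbind, strsplit(rownames(agg), " "))
    states_n <- cbind(as.numeric(uk[, 1]), as.numeric(uk[, 2]),
                      15 - as.numeric(uk[, 1]) - as.numeric(uk[, 2]))
    probs <- as.numeric(agg)
  }
  final_win <- sum(probs * tokens_likelihood(states_n[, 1], states_n[, 2],
                                             states_n[, 3]))
  expect_equal(final_win, 0.5)
})

test_that("tokens context encodes the post-decision animation timing", {
  slow <- make_tokens_context("slow", Rc = 2, cost = 0.5)
  fast <- make_tokens_context("fast", Rc = 2, cost = 0.5)
  t_n <- 0.2 * (0:15)
  # animation time at n = 0: 15 tokens at 170 ms vs 20 ms
  expect_equal(context_iti(slow, 0) - slow$base_iti, 15 * 0.17)
  expect_equal(context_iti(fast, 0) - fast$base_iti, 15 * 0.02)
  expect_equal(context_iti(slow, 3), slow$base_iti)  # n = 15: no animation
  expect_true(all(diff(context_iti(slow, t_n)) < 0))
  expect_true(all(diff(context_iti(fast, t_n)) < 0))
  expect_equal(slow$reward_incorrect, -1)
  expect_error(context_iti(slow, 3.4), "0..15")
})

test_that("schedules export as CSV without gaps", {
  ctx <- make_reward_change_schedule(3, 8, quick_base())
  f <- withr::local_tempfile(fileext = ".csv")
  write_schedule_csv(ctx, f)
  df <- read.csv(f)
  expect_equal(nrow(df), round(ctx$t_final / ctx$delta_t) + 1)
  expect_false(anyNA(df$Rc))
  expect_equal(df$Rc[df$t == 0.5], 8)
})
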