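# Shared fixtures: coarse grids and short windows keep unit tests fast;
# the acceptance suite exercises the package defaults.

quick_grid <- function(n = 201L) belief_grid(n)

quick_base <- function(window = 1) {
  base_context(m = 5, delta_t = 0.02, window = window)
}

quick_solve <- function(ctx, grid = quick_grid(), ...) {
  solve_reward_rate(ctx, grid = grid, ...)
}

# independent combinatorial oracle for the tokens-task state likelihood:
# count the down-token assignments of the remaining C center tokens that
# leave the lower target with at most 7 tokens
tokens_likelihood_oracle <- function(U, L, C) {
  ks <- 0:C
  ok <- (L + ks) <= 7
  sum(choose(C, ks)[ok]) / 2^C
}

all_token_states <- function() {
  out <- list()
  for (C in 0:15) for (U in 0:(15 - C)) {
    out[[length(out) + 1L]] <- c(U = U, L = 15 - C - U, C = C)
  }
  do.call(rbind, out)
}

make_trace <- function(t, upper, window = max(t), change_times = numeric(0),
                       grid_step = 0.002) {
  lower <- ifelse(is.finite(upper), 1 - upper, -Inf)
  structure(
    data.frame(t = t, theta_p_upper = upper, theta_p_lower = lower,
               theta_llr_upper = ifelse(is.finite(upper),
                                        log(upper / (1 - upper)), Inf),
               theta_llr_lower = ifelse(is.finite(lower),
                                        log(lower / (1 - lower)), -Inf)),
    class = c("threshold_trace", "data.frame"),
    window = window, change_times = change_times, grid_step = grid_step
  )
}
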