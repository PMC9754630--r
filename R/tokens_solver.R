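# Backward induction for the tokens task.  The state space is the set of
# reachable token configurations, indexed by (n, U): n tokens moved so far,
# U of them to the upper target.  Waiting propagates to the two equally
# likely successors; at n = 15 the choice is forced.

tokens_state_likelihoods <- function(n_tokens = 15L) {
  # p_mat[n + 1, U + 1] = Pr(top wins | n moved, U up); NA if unreachable
  p_mat <- matrix(NA_real_, n_tokens + 1L, n_tokens + 1L)
  for (n in 0:n_tokens) {
    U <- 0:n
    p_mat[n + 1L, U + 1L] <- tokens_likelihood(U, n - U, n_tokens - n)
  }
  p_mat
}

tokens_backward_induction <- function(context, rho, full = TRUE) {
  stopifnot(context$kind == "tokens")
  n_tok <- context$n_tokens
  dt <- context$delta_t
  Rc <- context_reward(context, 0)
  Ri <- context$reward_incorrect
  cost <- context_cost(context, 0)
  p_mat <- tokens_state_likelihoods(n_tok)
  iti_n <- context_iti(context, dt * (0:n_tok))
  V <- matrix(NA_real_, n_tok + 1L, n_tok + 1L)
  A <- matrix(NA_integer_, n_tok + 1L, n_tok + 1L)

  commit <- function(n) {
    p <- p_mat[n + 1L, 1:(n + 1L)]
    vp <- Rc * p + Ri * (1 - p) - iti_n[n + 1L] * rho
    vm <- Rc * (1 - p) + Ri * p - iti_n[n + 1L] * rho
    plus <- ifelse(p >= 0.5, vp >= vm, vp > vm)
    list(v = ifelse(plus, vp, vm), a = ifelse(plus, 1L, 2L))
  }

  cm <- commit(n_tok)
  V[n_tok + 1L, 1:(n_tok + 1L)] <- cm$v
  A[n_tok + 1L, 1:(n_tok + 1L)] <- cm$a
  for (n in (n_tok - 1L):0) {
    idx <- 1:(n + 1L)
    vw <- 0.5 * (V[n + 2L, idx] + V[n + 2L, idx + 1L]) - cost * dt - rho * dt
    cm <- commit(n)
    take_commit <- cm$v >= vw
    V[n + 1L, idx] <- ifelse(take_commit, cm$v, vw)
    A[n + 1L, idx] <- ifelse(take_commit, cm$a, 3L)
  }
  out <- list(kind = "tokens", v0 = V[1L, 1L], rho = rho,
              t = dt * (0:n_tok), context = context,
              state_likelihood = p_mat)
  if (full) {
    out$value <- V
    out$action <- A
  }
  structure(out, class = "value_solution")
}

tokens_extract_thresholds <- function(solution) {
  ctx <- solution$context
  n_tok <- ctx$n_tokens
  p_mat <- solution$state_likelihood
  A <- solution$action
  up <- lo <- nt_up <- rep(NA_real_, n_tok + 1L)
  for (n in 0:n_tok) {
    idx <- 1:(n + 1L)
    p <- p_mat[n + 1L, idx]
    a <- A[n + 1L, idx]
    i_up <- which(a == 1L)
    i_lo <- which(a == 2L)
    up[n + 1L] <- if (length(i_up)) p[i_up[1]] else Inf
    lo[n + 1L] <- if (length(i_lo)) p[i_lo[length(i_lo)]] else -Inf
    if (identical(up[n + 1L], 0.5)) lo[n + 1L] <- 0.5  # commitment tie at 1/2
    nt_up[n + 1L] <- if (length(i_up)) 2 * (i_up[1] - 1L) - n else Inf
  }
  clamp <- function(p) pmin(pmax(p, 1e-9), 1 - 1e-9)
  structure(
    data.frame(
      t = solution$t,
      theta_p_upper = up,
      theta_p_lower = lo,
      theta_llr_upper = ifelse(is.finite(up), p_to_llr(clamp(up)), Inf),
      theta_llr_lower = ifelse(is.finite(lo), p_to_llr(clamp(lo)), -Inf)
    ),
    class = c("threshold_trace", "data.frame"),
    window = ctx$window,
    change_times = numeric(0),
    grid_step = 0.02,
    n_t = nt_up,
    kind = "tokens"
  )
}
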