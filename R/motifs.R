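# Qualitative classification of threshold time courses into dynamic motifs.
#
# The classifier operationalizes a visual taxonomy: an "infinite epoch" is
# at least two consecutive timesteps on which waiting is optimal at every
# belief; a "collapse to zero" is the upper threshold coming within one grid
# cell of p = 0.5 shortly before a scheduled change; local extrema are
# counted on the trace after compressing it to direction changes larger
# than one grid cell, which suppresses discretization chatter.

# compress a numeric trace into significant turning points; returns the
# sequence of signed moves (+1 up, -1 down) with amplitude > tol
significant_moves <- function(x, tol) {
  moves <- integer(0)
  if (length(x) < 2) return(moves)
  anchor <- x[1]
  dir <- 0L
  for (v in x[-1]) {
    d <- v - anchor
    if (dir == 0L) {
      if (abs(d) > tol) {
        dir <- sign(d)
        moves <- c(moves, dir)
        anchor <- v
      }
    } else if (sign(d) == dir) {
      anchor <- max(anchor * dir, v * dir) * dir  # extend current move
    } else if (abs(d) > tol) {
      dir <- -dir
      moves <- c(moves, dir)
      anchor <- v
    }
  }
  moves
}

smooth3 <- function(x) {
  if (length(x) < 3) return(x)
  s <- stats::filter(x, rep(1 / 3, 3), sides = 2)
  s[1] <- x[1]
  s[length(x)] <- x[length(x)]
  as.numeric(s)
}

#' Classify a threshold trace into a dynamic motif
#'
#' Assigns one qualitative label to the time course of the upper decision
#' threshold on the analysis window.  For the continuous-evidence tasks the
#' label is derived from (a) infinite-threshold epochs, (b) collapse of the
#' threshold to p = 0.5 at a scheduled change, and (c) the number and sign
#' of significant direction changes; for the tokens task the trace is first
#' reduced to a parity-free envelope in token-lead coordinates (adjacent
#' steps alternate reachable beliefs), the degenerate start and forced-end
#' steps are dropped, and labels follow the count of threshold-increase
#' episodes.
#'
#' Possible labels: `wait-then-respond`, `collapse-to-zero-before-change`,
#' `nonmonotone-dip`, `nonmonotone-rise`, `nonmonotone-mixed`,
#' `monotone-collapsing`, `constant-like`, `stepped`.
#'
#' @param trace A `threshold_trace` from [extract_thresholds()].
#' @param change_times Scheduled change times (defaults to the trace
#'   attribute).
#' @param window Analysis window (defaults to the trace attribute).
#' @return A single character label.
#' @export
classify_motif <- function(trace, change_times = NULL, window = NULL) {
  stopifnot(inherits(trace, "threshold_trace"))
  if (is.null(change_times)) change_times <- attr(trace, "change_times")
  if (is.null(window)) window <- attr(trace, "window")
  if (identical(attr(trace, "kind"), "tokens")) {
    return(classify_tokens_motif(trace))
  }
  w <- trace[trace$t <= window + 1e-12, ]
  th <- w$theta_p_upper
  cell <- attr(trace, "grid_step")
  if (all(!is.finite(th))) {
    stop("degenerate trace: thresholds are infinite on the whole window")
  }
  fin <- is.finite(th)
  runs <- rle(fin)
  # leading finite stubs shorter than 2 steps are chatter, not an epoch
  lead_inf <- !runs$values[1] || (runs$values[1] && runs$lengths[1] < 2L &&
                                    length(runs$values) > 1L)
  has_inf_epoch <- any(!runs$values & runs$lengths >= 2L)
  if (has_inf_epoch && lead_inf) {
    return("wait-then-respond")
  }
  touches_zero <- function() {
    if (!length(change_times)) return(FALSE)
    for (ct in change_times) {
      pre <- which(w$t >= ct - 0.15 * window & w$t <= ct + 1e-12 & fin)
      if (length(pre) && any(th[pre] - 0.5 <= cell + 1e-12)) return(TRUE)
    }
    FALSE
  }
  if (has_inf_epoch) {
    # finite start, waiting epoch later in the trial
    last_run_inf <- !runs$values[length(runs$values)]
    if (last_run_inf && touches_zero()) return("collapse-to-zero-before-change")
    return("nonmonotone-mixed")
  }
  if (touches_zero()) return("collapse-to-zero-before-change")
  s <- smooth3(th)
  moves <- significant_moves(s, tol = cell)
  if (length(moves) == 0L) return("constant-like")
  if (length(moves) == 1L) {
    return(if (moves == 1L) "stepped" else "monotone-collapsing")
  }
  if (length(moves) == 2L) {
    return(if (moves[1] == -1L) "nonmonotone-dip" else "nonmonotone-rise")
  }
  "nonmonotone-mixed"
}

classify_tokens_motif <- function(trace) {
  up <- trace$theta_p_upper
  nt <- attr(trace, "n_t")
  n_tok <- length(up) - 1L
  # treat "commit only when the outcome is already certain" like an infinite
  # threshold for undecided beliefs
  eff <- ifelse(is.finite(up) & up < 1, nt, Inf)
  # parity-free lower envelope, dropping the degenerate start state (n = 0,
  # a single p = 0.5 state) and the forced terminal step
  idx <- 2:n_tok                      # token steps 1 .. 14
  x <- eff[idx]
  env <- pmin(x[-length(x)], x[-1])
  if (all(!is.finite(env))) {
    stop("degenerate trace: thresholds are infinite at every token step")
  }
  r <- rle(is.finite(env))
  if (!r$values[1] && r$lengths[1] >= 2L) return("wait-then-respond")
  # drop a trailing all-wait run, then count significant rises/falls
  if (!r$values[length(r$values)]) {
    env <- env[seq_len(length(env) - r$lengths[length(r$values)])]
  }
  env <- env[is.finite(env)]
  moves <- significant_moves(env, tol = 0.5)  # token-lead units
  rises <- sum(moves == 1L)
  if (rises == 0L) return("monotone-collapsing")
  if (rises == 1L && moves[1] == 1L) return("nonmonotone-rise")
  "nonmonotone-mixed"
}

#' Map dynamic motifs over a task-parameter grid
#'
#' Solves the DP and classifies the threshold motif for every cell of a
#' two-parameter grid: pre/post-change rewards (`"reward"`), pre/post-change
#' drifts (`"snr"`), or reward/cost combinations for the tokens task
#' (`"tokens"`).  Reward-rate solutions warm-start their neighbours.
#'
#' @param task_kind `"reward"`, `"snr"` or `"tokens"`.
#' @param param1,param2 Grid values: R1 and R2 (reward), mu1 and mu2 (snr),
#'   or Rc and c (tokens).
#' @param base Shared settings ([base_context()]) for the continuous tasks.
#' @param speed Tokens animation speed (tokens only).
#' @param Ri Punishment (tokens only; default -1).
#' @param grid Belief grid for the continuous tasks.
#' @return A data.frame with columns `param1`, `param2`, `label`, `rho`,
#'   `failed`; attribute `labels` holds the distinct motif labels found.
#' @examples
#' \donttest{
#' mm <- motif_map("tokens", param1 = c(1, 4), param2 = c(0.5, 2))
#' attr(mm, "labels")
#' }
#' @export
motif_map <- function(task_kind = c("reward", "snr", "tokens"),
                      param1, param2, base = base_context(),
                      speed = c("slow", "fast"), Ri = -1,
                      grid = belief_grid()) {
  task_kind <- match.arg(task_kind)
  speed <- match.arg(speed)
  cells <- expand.grid(param1 = param1, param2 = param2,
                       KEEP.OUT.ATTRS = FALSE)
  labels <- character(nrow(cells))
  rhos <- rep(NA_real_, nrow(cells))
  failed <- logical(nrow(cells))
  transfer_cache <- new.env(parent = emptyenv())
  get_transfer <- function(ctx) {
    key <- paste0("m", paste(signif(c(ctx$mu$breaks, ctx$mu$values), 12),
                             collapse = "_"))
    if (!is.null(transfer_cache[[key]])) return(transfer_cache[[key]])
    tr <- context_transfer_matrices(ctx, grid)
    transfer_cache[[key]] <- tr
    tr
  }
  rho_prev <- NULL
  for (i in seq_len(nrow(cells))) {
    ctx <- switch(task_kind,
      reward = make_reward_change_schedule(cells$param1[i], cells$param2[i],
                                           base = base),
      snr = make_snr_change_schedule(cells$param1[i], cells$param2[i],
                                     base = base),
      tokens = make_tokens_context(speed, Rc = cells$param1[i],
                                   cost = cells$param2[i], Ri = Ri)
    )
    res <- tryCatch({
      sol <- if (task_kind == "tokens") {
        solve_reward_rate(ctx, rho_init = rho_prev)
      } else {
        solve_reward_rate(ctx, grid = grid, transfer = get_transfer(ctx),
                          rho_init = rho_prev)
      }
      rho_prev <- sol$rho
      list(label = classify_motif(extract_thresholds(sol)), rho = sol$rho)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[i] <- TRUE
      labels[i] <- NA_character_
      warning("cell (", cells$param1[i], ", ", cells$param2[i], ") failed: ",
              conditionMessage(res), call. = FALSE)
    } else {
      labels[i] <- res$label
      rhos[i] <- res$rho
    }
  }
  out <- data.frame(param1 = cells$param1, param2 = cells$param2,
                    label = labels, rho = rhos, failed = failed)
  attr(out, "labels") <- sort(unique(labels[!is.na(labels)]))
  attr(out, "task_kind") <- task_kind
  out
}
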