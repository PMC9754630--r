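# Synthetic tokens-task data: token-sequence generation, synthetic-subject
# datasets produced by the observer models, cohort generation, and the CSV
# dialect consumed by the fitting pipeline.

#' Generate random token sequences
#'
#' Each trial is 15 independent fair-coin token movements (+1 = up,
#' -1 = down).
#'
#' @param n_trials Number of trials.
#' @param seed Optional integer seed.
#' @return An integer matrix (`n_trials` x 15) of +1/-1 moves.
#' @export
generate_token_sequences <- function(n_trials, seed = NULL) {
  if (n_trials < 1) stop("n_trials must be positive")
  if (!is.null(seed)) set.seed(seed)
  matrix(sample(c(-1L, 1L), n_trials * 15L, replace = TRUE),
         nrow = n_trials, ncol = 15L)
}

#' Subject dataset for the tokens task
#'
#' Bundles one subject's trials: the token sequences shown and the binned
#' response time (0..15 token movements) of each trial, plus the task speed
#' condition.
#'
#' @param sequences Matrix of token moves (+1/-1, trials x 15).
#' @param rt_bin Integer vector of response bins in 0..15 (one per trial).
#' @param speed `"slow"` or `"fast"`.
#' @param subject_id Identifier string.
#' @return A `subject_dataset`.
#' @export
subject_dataset <- function(sequences, rt_bin, speed = c("slow", "fast"),
                            subject_id = "s1") {
  speed <- match.arg(speed)
  sequences <- as.matrix(sequences)
  if (ncol(sequences) != 15L) stop("sequences must have 15 token moves per trial")
  if (!all(sequences %in% c(-1L, 1L))) stop("token moves must be +1 or -1")
  rt_bin <- as.integer(rt_bin)
  if (length(rt_bin) != nrow(sequences)) {
    stop("one response bin per trial required")
  }
  if (any(rt_bin < 0L | rt_bin > 15L)) stop("rt_bin must lie in 0..15")
  structure(list(sequences = sequences, rt_bin = rt_bin, speed = speed,
                 subject_id = subject_id),
            class = "subject_dataset")
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf("subject_dataset %s: %d trials (%s task)\n",
              x$subject_id, length(x$rt_bin), x$speed))
  invisible(x)
}

#' Generate a synthetic subject from an observer model
#'
#' Simulates a subject performing the tokens task with the given model and
#' noise parameters: fresh fair-coin token sequences, model-determined
#' responses, motor-filtered and binned response times.
#'
#' @param params A `model_params` object (generator and noise parameters).
#' @param speed `"slow"` or `"fast"`.
#' @param n_trials Number of trials.
#' @param seed Optional integer seed.
#' @param subject_id Identifier string.
#' @return A `subject_dataset`; attribute `generator` records the model
#'   kind and parameters.
#' @export
generate_synthetic_subject <- function(params, speed = c("slow", "fast"),
                                       n_trials = 500L, seed = NULL,
                                       subject_id = "s1") {
  speed <- match.arg(speed)
  info <- model_par_info(model_kind(params))
  vals <- unlist(params[info$names])
  if (any(vals < info$lower - 1e-12) || any(vals > info$upper + 1e-12)) {
    stop("generator parameters outside the prior bounds")
  }
  if (!is.null(seed)) set.seed(seed)
  sequences <- generate_token_sequences(n_trials)
  trials <- simulate_tokens_trials(params, speed, sequences = sequences)
  out <- subject_dataset(sequences, trials$rt_bin, speed, subject_id)
  attr(out, "generator") <- list(model_kind = model_kind(params),
                                 params = params)
  out
}

#' Generate a synthetic cohort
#'
#' Draws a cohort of synthetic subjects whose generator models and noise
#' parameters are sampled from the given specification, emulating the
#' structure of a multi-subject tokens-task dataset (slow/fast conditions,
#' 16 response bins, several hundred trials per subject).
#'
#' @param n_subjects Number of subjects.
#' @param trials_per_subject Trials per subject.
#' @param model_mix Named proportions over generator classes
#'   (`nb`, `const`, `ugm`); must sum to 1.
#' @param speed_mix Named proportions over speed conditions.
#' @param param_sampler Function `(model_kind)` returning a `model_params`
#'   draw; defaults to a spread of threshold-governing parameters with
#'   moderate noise.
#' @param master_seed Integer seed controlling the whole cohort.
#' @return A list of `subject_dataset` objects with `generator` attributes.
#' @export
generate_cohort <- function(n_subjects = 20L, trials_per_subject = 500L,
                            model_mix = c(nb = 1, const = 0, ugm = 0),
                            speed_mix = c(slow = 0.5, fast = 0.5),
                            param_sampler = default_param_sampler,
                            master_seed = 1L) {
  if (abs(sum(model_mix) - 1) > 1e-9) stop("model_mix must sum to 1")
  if (abs(sum(speed_mix) - 1) > 1e-9) stop("speed_mix must sum to 1")
  if (n_subjects < 1 || trials_per_subject < 1) stop("counts must be positive")
  set.seed(master_seed)
  kinds <- sample(names(model_mix), n_subjects, replace = TRUE,
                  prob = model_mix)
  speeds <- sample(names(speed_mix), n_subjects, replace = TRUE,
                   prob = speed_mix)
  seeds <- sample.int(2^30, n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    set.seed(seeds[i])
    params <- param_sampler(kinds[i])
    generate_synthetic_subject(params, speeds[i],
                               n_trials = trials_per_subject,
                               subject_id = sprintf("synth%02d", i))
  })
}

#' @rdname generate_cohort
#' @param kind Generator model kind.
#' @export
default_param_sampler <- function(kind) {
  sy <- runif(1, 0.5, 2.5)
  smn <- runif(1, 0.02, 0.12)
  switch(kind,
    nb = nb_params(Rc = runif(1, 1, 8), cost = runif(1, 0.2, 3),
                   sigma_y = sy, sigma_mn = smn),
    const = const_params(theta0 = runif(1, 0.5, 4), sigma_y = sy,
                         sigma_mn = smn),
    # canonical urgency gating: a fixed ~200 ms low-pass filter; sensory
    # noise acts on the filter output E, which lives in [-1/2, 1/2], an
    # order of magnitude below the LLR-scale noise of the other two
    # models.  The bound scale theta0/gain is kept below ~0.8 so the
    # collapsing bound actually comes within reach of E before the forced
    # deadline (an observer whose bound never does responds only at the
    # deadline and carries no threshold information).
    ugm = {
      ratio <- exp(runif(1, log(0.02), log(1.2)))
      gain <- exp(runif(1, log(0.5), log(4)))
      ugm_params(theta0 = ratio * gain, gain = gain, tau = 0.2,
                 sigma_y = runif(1, 0.05, 0.4), sigma_mn = smn)
    },
    stop("unknown model kind")
  )
}

#' Read and write the subject-data CSV dialect
#'
#' One row per trial with columns `subject_id`, `speed`, `trial`,
#' `move_1`..`move_15` (letters `U`/`D`) and `rt_bin`.  A write-then-read
#' round trip reproduces the dataset exactly.
#'
#' @param data A `subject_dataset`.
#' @param file Path to the CSV file.
#' @return `write_subject_csv` returns `file` invisibly;
#'   `read_subject_csv` returns a list of `subject_dataset` (one per
#'   subject id present).
#' @export
write_subject_csv <- function(data, file) {
  if (inherits(data, "subject_dataset")) data <- list(data)
  rows <- lapply(data, function(d) {
    mv <- matrix(ifelse(d$sequences > 0, "U", "D"), nrow(d$sequences), 15L)
    colnames(mv) <- sprintf("move_%d", 1:15)
    data.frame(subject_id = d$subject_id, speed = d$speed,
               trial = seq_along(d$rt_bin), mv, rt_bin = d$rt_bin)
  })
  write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_subject_csv
#' @export
read_subject_csv <- function(file) {
  if (!file.exists(file)) stop("subject data file not found: ", file)
  df <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("subject_id", "speed", "trial", sprintf("move_%d", 1:15), "rt_bin")
  if (!all(need %in% names(df))) {
    stop("malformed subject CSV: missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  lapply(split(df, df$subject_id), function(d) {
    d <- d[order(d$trial), ]
    mv <- unname(as.matrix(d[sprintf("move_%d", 1:15)]))
    subject_dataset(matrix(ifelse(mv == "U", 1L, -1L), nrow(mv)), d$rt_bin,
                    speed = d$speed[1], subject_id = d$subject_id[1])
  })
}
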