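#' Task configuration for the synthetic mixed-gambles experiment
#'
#' Describes the gamble grid and scan timing. Gains and losses are crossed
#' orthogonally; in the `equal_range` condition the loss levels span the same
#' range as the gains, while in `equal_indifference` the loss range is half
#' the gain range (consistent with typical loss-aversion estimates near 2).
#'
#' @param condition `"equal_range"` or `"equal_indifference"`.
#' @param gain_levels currency magnitudes of potential gains.
#' @param loss_levels currency magnitudes of potential losses; by default
#'   derived from `condition` (equal to `gain_levels`, or scaled to half
#'   their span).
#' @param n_trials_per_run,n_runs trial counts (default 64 trials x 4 runs;
#'   64 is the full 8x8 crossing of the default levels).
#' @param trial_duration trial (boxcar) duration in seconds (default 4).
#' @param iti_range uniform inter-trial interval bounds in seconds.
#' @param TR repetition time in seconds.
#' @param initial_rest,final_rest padding at run boundaries (seconds).
#' @return list of class `"task_config"`.
#' @export
task_config <- function(condition = c("equal_range", "equal_indifference"),
                        gain_levels = seq(5, 40, by = 5),
                        loss_levels = NULL,
                        n_trials_per_run = 64, n_runs = 4,
                        trial_duration = 4, iti_range = c(2, 6),
                        TR = 1, initial_rest = 10, final_rest = 16) {
  condition <- match.arg(condition)
  stopifnot(length(gain_levels) > 0, all(gain_levels >= 0),
            n_trials_per_run > 0, n_runs > 0, trial_duration > 0, TR > 0,
            iti_range[1] > 0, iti_range[2] >= iti_range[1])
  if (is.null(loss_levels)) {
    loss_levels <- if (condition == "equal_range") gain_levels
                   else gain_levels / 2
  }
  structure(list(condition = condition, gain_levels = gain_levels,
                 loss_levels = loss_levels,
                 n_trials_per_run = n_trials_per_run, n_runs = n_runs,
                 trial_duration = trial_duration, iti_range = iti_range,
                 TR = TR, initial_rest = initial_rest,
                 final_rest = final_rest),
            class = "task_config")
}

#' Generate gamble schedules for one participant
#'
#' Draws trials from the full gain-by-loss crossing (without replacement
#' unless `replace = TRUE`), shuffles them per run, and lays out onsets with
#' uniformly jittered inter-trial intervals. Fully reproducible given the
#' seed.
#'
#' @param config a [task_config()].
#' @param seed integer seed.
#' @param replace sample crossings with replacement when the requested trial
#'   count exceeds the number of unique crossings.
#' @return data frame with `run`, `trial`, `onset`, `duration`, `gain`,
#'   `loss`, plus an attribute `n_volumes` (per-run volume count).
#' @export
generate_gambles <- function(config, seed = 1, replace = FALSE) {
  stopifnot(inherits(config, "task_config"))
  set.seed(seed)
  cross <- expand.grid(gain = config$gain_levels, loss = config$loss_levels)
  n_cross <- nrow(cross)
  nt <- config$n_trials_per_run
  if (nt > n_cross && !replace)
    stop("n_trials_per_run (", nt, ") exceeds the ", n_cross,
         " unique gain x loss crossings; set replace = TRUE to resample")
  runs <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    idx <- sample.int(n_cross, nt, replace = replace)
    iti <- stats::runif(nt, config$iti_range[1], config$iti_range[2])
    onset <- config$initial_rest +
      cumsum(c(0, head(iti, -1) + config$trial_duration))
    runs[[r]] <- data.frame(run = r, trial = seq_len(nt), onset = onset,
                            duration = config$trial_duration,
                            gain = cross$gain[idx], loss = cross$loss[idx])
  }
  out <- do.call(rbind, runs)
  run_end <- max(out$onset[out$run == config$n_runs]) +
    config$trial_duration + config$final_rest
  attr(out, "n_volumes") <- ceiling(
    (tapply(out$onset, out$run, max) + config$trial_duration +
       config$final_rest) / config$TR)
  attr(out, "config") <- config
  out
}

#' Simulate one participant's behaviour
#'
#' Generates gamble schedules and samples choices from a known choice model:
#' Bernoulli accepts at the model's acceptance probability, with 4-level
#' responses split by the confidence threshold `theta` on the probability of
#' being correct.
#'
#' @param config a [task_config()].
#' @param true_model a `choice_model` (e.g. [true_choice_model()]) holding
#'   the generating coefficients.
#' @param seed integer seed (governs both schedule and choices).
#' @param theta strong/weak confidence threshold (default 0.75).
#' @return trial data frame with gamble, timing, `accept`, `response4`, and
#'   the generating model's trial values (`sv_true`, `p_accept_true`).
#' @export
simulate_participant <- function(config, true_model, seed = 1, theta = 0.75) {
  g <- generate_gambles(config, seed = seed)
  ch <- simulate(true_model, seed = seed + 1L, newdata = g, theta = theta)
  g$accept <- ch$accept
  g$response4 <- ch$response4
  g$sv_true <- stats::predict(true_model, newdata = g, type = "sv")
  g$p_accept_true <- stats::predict(true_model, newdata = g, type = "response")
  g
}

#' Draw a synthetic cohort of choice models
#'
#' Participant-level generating coefficients: `beta_gains` lognormal around
#' `mean_beta_gain`, `beta_losses = -loss_aversion * beta_gains` with
#' participant-level loss aversion drawn around `mean_loss_aversion` (about
#' 2, the canonical loss-aversion estimate), and a small intercept.
#'
#' @param n_subjects cohort size.
#' @param mean_beta_gain,mean_loss_aversion,intercept_sd population
#'   parameters.
#' @param seed integer seed.
#' @return list of `choice_model` objects (class `true_choice_model` inputs).
#' @export
cohort_models <- function(n_subjects = 24, mean_beta_gain = 0.1,
                          mean_loss_aversion = 2, intercept_sd = 0.2,
                          seed = 1) {
  set.seed(seed)
  bg <- mean_beta_gain * exp(stats::rnorm(n_subjects, 0, 0.25))
  la <- mean_loss_aversion * exp(stats::rnorm(n_subjects, 0, 0.2))
  ic <- stats::rnorm(n_subjects, 0, intercept_sd)
  lapply(seq_len(n_subjects), function(i)
    true_choice_model(bg[i], -la[i] * bg[i], ic[i]))
}
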