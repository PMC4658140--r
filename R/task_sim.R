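#' Incentive-delay task configuration
#'
#' Defaults reproduce the study design: four cue types (+5, +1, -1, -5
#' points), 4 blocks of 50 trials (200 trials), a response deadline adjusted
#' online by +/-33 ms (shortened after a success, lengthened after a
#' failure, independent of cue type), and a fixation interval jittered
#' between 0.5 and 2 s. The staircase holds the success rate near 50% by
#' converging on the responder's median reaction time.
#'
#' @param cue_set signed cue magnitudes (points at stake).
#' @param n_blocks number of blocks.
#' @param trials_per_block trials per block.
#' @param step_ms staircase step (ms).
#' @param initial_deadline_ms starting response deadline (ms).
#' @param fixation_jitter_ms `(min, max)` fixation interval (ms).
#' @param cue_duration_ms cue presentation time (ms).
#' @param carry_over_blocks logical; keep the deadline across block breaks.
#' @param deadline_floor_ms lower bound keeping the staircase well-defined.
#' @return a `task_config`.
#' @export
task_config <- function(cue_set = c(5, 1, -1, -5), n_blocks = 4L,
                        trials_per_block = 50L, step_ms = 33,
                        initial_deadline_ms = 400,
                        fixation_jitter_ms = c(500, 2000),
                        cue_duration_ms = 1000, carry_over_blocks = TRUE,
                        deadline_floor_ms = 1) {
  stopifnot(step_ms > 0, trials_per_block >= 1, n_blocks >= 1,
            fixation_jitter_ms[1] <= fixation_jitter_ms[2],
            initial_deadline_ms > 0, length(cue_set) >= 1)
  structure(list(cue_set = cue_set, n_blocks = as.integer(n_blocks),
                 trials_per_block = as.integer(trials_per_block),
                 step_ms = step_ms, initial_deadline_ms = initial_deadline_ms,
                 fixation_jitter_ms = fixation_jitter_ms,
                 cue_duration_ms = cue_duration_ms,
                 carry_over_blocks = carry_over_blocks,
                 deadline_floor_ms = deadline_floor_ms), class = "task_config")
}

#' Simulated responder
#'
#' Reaction times follow a shifted log-normal,
#' `rt = shift_ms + exp(N(meanlog, sdlog))`, supported on positive times.
#' The defaults give a median near 300 ms, the scale healthy adults produce
#' in speeded reward tasks. `sdlog = 0` gives a constant-RT responder;
#' `shift_ms = Inf` one that never beats any deadline.
#'
#' @param shift_ms non-negative shift (ms).
#' @param meanlog,sdlog log-normal parameters of the variable part.
#' @return a `responder`.
#' @export
responder <- function(shift_ms = 150, meanlog = log(150), sdlog = 0.35) {
  stopifnot(shift_ms >= 0, sdlog >= 0)
  structure(list(shift_ms = shift_ms, meanlog = meanlog, sdlog = sdlog),
            class = "responder")
}

#' @keywords internal
responder_median <- function(resp) resp$shift_ms + exp(resp$meanlog)

draw_rt <- function(resp, n) {
  if (is.infinite(resp$shift_ms)) return(rep(Inf, n))
  resp$shift_ms + stats::rlnorm(n, resp$meanlog, resp$sdlog)
}

#' Run one simulated task session
#'
#' Cues are drawn uniformly from the cue set. A trial succeeds iff the drawn
#' reaction time is strictly below the current deadline. Scoring follows the
#' task's asymmetric contingencies: success on a positive cue wins its
#' magnitude; failure on a positive cue wins nothing; success on a negative
#' cue loses nothing; failure on a negative cue loses its magnitude. After
#' each trial the deadline moves by `-step_ms` on success, `+step_ms` on
#' failure, regardless of cue type, floored at `deadline_floor_ms`.
#'
#' @param config a [task_config()].
#' @param resp a [responder()].
#' @param seed integer seed; the whole session is reproducible given it.
#' @return data.frame of trial records: `index`, `block`, `cue_valence`
#'   (+1/-1), `cue_magnitude`, `deadline_ms` (at trial start), `rt_ms`,
#'   `success`, `points_delta`, `running_total`.
#' @export
run_session <- function(config = task_config(), resp = responder(), seed = 1L) {
  n_trials <- config$n_blocks * config$trials_per_block
  with_seed(seed, {
    cues <- sample(config$cue_set, n_trials, replace = TRUE)
    rts <- draw_rt(resp, n_trials)
    deadline_at <- success <- numeric(n_trials)
    deadline <- config$initial_deadline_ms
    for (i in seq_len(n_trials)) {
      if (!config$carry_over_blocks && i > 1L &&
          (i - 1L) %% config$trials_per_block == 0L) {
        deadline <- config$initial_deadline_ms
      }
      deadline_at[i] <- deadline
      success[i] <- rts[i] < deadline
      deadline <- max(config$deadline_floor_ms,
                      deadline + if (success[i]) -config$step_ms else config$step_ms)
    }
    success <- as.logical(success)
    delta <- ifelse(cues > 0, ifelse(success, cues, 0),
                    ifelse(success, 0, cues))
    data.frame(index = seq_len(n_trials),
               block = (seq_len(n_trials) - 1L) %/% config$trials_per_block + 1L,
               cue_valence = sign(cues), cue_magnitude = abs(cues),
               deadline_ms = deadline_at, rt_ms = rts, success = success,
               points_delta = delta, running_total = cumsum(delta))
  })
}

#' Success rate after a burn-in
#'
#' Fraction of successful trials after discarding the first
#' `discard_burn_in` trials (default one block, over which the staircase is
#' still converging from its starting deadline).
#'
#' @param trials a trial data.frame from [run_session()].
#' @param discard_burn_in number of leading trials to drop.
#' @return proportion of successes among retained trials.
#' @export
success_rate <- function(trials, discard_burn_in = 50L) {
  keep <- trials[trials$index > discard_burn_in, , drop = FALSE]
  if (!nrow(keep)) stop("no trials left after the burn-in", call. = FALSE)
  mean(keep$success)
}

#' Summarize behaviour by run, valence and magnitude
#'
#' Cell means of reaction time plus success and trial counts for every
#' run (block) x valence x magnitude cell, the layout behavioural ANOVAs use.
#'
#' @param trials a trial data.frame from [run_session()].
#' @return data.frame with `run`, `cue_valence`, `cue_magnitude`,
#'   `mean_rt_ms`, `n_success`, `n_trials`.
#' @export
summarize_behavior <- function(trials) {
  finite_rt <- ifelse(is.finite(trials$rt_ms), trials$rt_ms, NA_real_)
  by <- list(run = trials$block, cue_valence = trials$cue_valence,
             cue_magnitude = trials$cue_magnitude)
  out <- stats::aggregate(finite_rt, by = by, FUN = mean, na.rm = TRUE)
  names(out)[4] <- "mean_rt_ms"
  out$n_success <- stats::aggregate(trials$success, by = by, FUN = sum)$x
  out$n_trials <- stats::aggregate(rep(1L, nrow(trials)), by = by, FUN = sum)$x
  out[order(out$run, out$cue_valence, out$cue_magnitude), ]
}

#' Write trial records as CSV
#'
#' @param trials a trial data.frame from [run_session()].
#' @param path output file.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}
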