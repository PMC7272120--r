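#' Behavioural session schedule parameters
#'
#' Defines one go/no-go detection session: interleaved stimulus and catch
#' trials delivered at randomized intervals. Defaults follow the task
#' design: about 100 trials per session (50 stimulus + 50 catch),
#' inter-trial intervals randomized between 3 and 30 s, a 3.5 s response
#' window, and a 2 s pre-stimulus lick lockout.
#'
#' @param n_stim_trials,n_catch_trials Trial counts.
#' @param iti_min,iti_max Bounds of the randomized inter-trial interval
#'   (seconds) added after each stimulus ends.
#' @param response_window Reward/scoring window after stimulus onset,
#'   seconds.
#' @param pre_stim_lockout Pre-onset lockout, seconds; licks here are
#'   flagged by the scorer.
#' @param stimulus A \code{\link{step_waveform_params}} object describing
#'   the stimulus delivered on stimulus trials.
#' @param seed Integer seed for schedule randomization, or NULL.
#' @return An object of class \code{session_schedule}.
#' @export
session_schedule <- function(n_stim_trials = 50, n_catch_trials = 50,
                             iti_min = 3, iti_max = 30,
                             response_window = 3.5, pre_stim_lockout = 2,
                             stimulus = step_waveform_params(),
                             seed = NULL) {
  if (iti_min < 0) stop("iti_min must be >= 0", call. = FALSE)
  if (iti_max < iti_min) stop("iti_max must be >= iti_min", call. = FALSE)
  if (response_window <= 0) stop("response_window must be > 0", call. = FALSE)
  if (n_stim_trials < 0 || n_catch_trials < 0 ||
      n_stim_trials + n_catch_trials < 1) {
    stop("need at least one trial", call. = FALSE)
  }
  stopifnot(inherits(stimulus, "step_waveform_params"))
  structure(
    list(n_stim_trials = as.integer(n_stim_trials),
         n_catch_trials = as.integer(n_catch_trials),
         iti_min = iti_min, iti_max = iti_max,
         response_window = response_window,
         pre_stim_lockout = pre_stim_lockout,
         stimulus = stimulus, seed = seed),
    class = "session_schedule"
  )
}

#' Generate a randomized trial table from a schedule
#'
#' Stimulus and catch trials are interleaved in random order; successive
#' onsets are separated by the stimulus duration plus a uniform random
#' interval in \code{[iti_min, iti_max]}. Catch trials have a virtual onset
#' and amplitude 0. Reproducible under the schedule seed.
#'
#' @param schedule A \code{\link{session_schedule}}.
#' @return A data.frame with columns \code{trial_id}, \code{type}
#'   ("stimulus" or "catch"), \code{onset_s}, \code{amplitude_c}.
#' @export
#' @examples
#' tt <- generate_schedule(session_schedule(seed = 1))
#' table(tt$type)   # 50 catch, 50 stimulus
generate_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "session_schedule"))
  n <- schedule$n_stim_trials + schedule$n_catch_trials
  stim_dur <- step_duration(schedule$stimulus)
  with_seed(if (is.null(schedule$seed)) NULL
            else child_seed(schedule$seed, "schedule"), {
    type <- sample(rep(c("stimulus", "catch"),
                       c(schedule$n_stim_trials, schedule$n_catch_trials)))
    gaps <- stim_dur + stats::runif(n, schedule$iti_min, schedule$iti_max)
    onsets <- schedule$pre_stim_lockout + cumsum(c(0, gaps[-n]))
    data.frame(
      trial_id = seq_len(n),
      type = type,
      onset_s = onsets,
      amplitude_c = ifelse(type == "stimulus",
                           step_amplitude(schedule$stimulus), 0),
      stringsAsFactors = FALSE
    )
  })
}
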