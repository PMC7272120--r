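#' Parametric go/no-go observer
#'
#' A generative model of a trained, water-restricted mouse in the thermal
#' detection task. Spontaneous licking is a homogeneous Poisson process;
#' on each stimulus trial the observer detects the stimulus with a
#' probability given by a saturating psychometric function of stimulus
#' amplitude, and a detection produces one stimulus-locked lick at a
#' log-normal latency.
#'
#' The detection probability at amplitude A (degC) is
#' \deqn{p(A) = guess + (1 - guess - lapse) / (1 + (threshold / A)^{slope})}
#' so \code{p(0) = guess}, \code{p(threshold)} is halfway between guess and
#' the lapse-limited asymptote, and \code{p} is non-decreasing in A.
#'
#' Defaults are tuned to the behaviour of a well-trained wild-type animal:
#' false-alarm rate about 0.16 in a 3.5 s window, asymptotic hit rate about
#' 0.93, session d-prime about 2.4 for a 10 degC step, a 1 degC perceptual
#' threshold, and mean first-lick latency near 0.85 s.
#'
#' @param baseline_lick_rate Spontaneous lick rate, Hz.
#' @param threshold_amp Psychometric midpoint amplitude, degC.
#' @param slope Dimensionless psychometric steepness (exponent).
#' @param lapse Probability of missing an arbitrarily strong stimulus.
#' @param guess Stimulus-independent detection probability.
#' @param latency_median Median of the log-normal first-lick latency, s.
#' @param latency_spread Log-scale standard deviation of the latency.
#' @return An object of class \code{observer_params}.
#' @export
observer_params <- function(baseline_lick_rate = 0.05, threshold_amp = 1,
                            slope = 3, lapse = 0.08, guess = 0,
                            latency_median = 0.8, latency_spread = 0.3) {
  probs <- c(lapse = lapse, guess = guess)
  if (any(probs < 0 | probs > 1) || lapse + guess > 1) {
    stop("lapse and guess must be probabilities with lapse + guess <= 1",
         call. = FALSE)
  }
  if (baseline_lick_rate < 0) stop("baseline_lick_rate must be >= 0",
                                   call. = FALSE)
  if (threshold_amp <= 0 || slope <= 0) {
    stop("threshold_amp and slope must be > 0", call. = FALSE)
  }
  if (latency_median <= 0 || latency_spread < 0) {
    stop("latency parameters must be positive", call. = FALSE)
  }
  structure(
    list(baseline_lick_rate = baseline_lick_rate,
         threshold_amp = threshold_amp, slope = slope,
         lapse = lapse, guess = guess,
         latency_median = latency_median, latency_spread = latency_spread),
    class = "observer_params"
  )
}

#' @rdname observer_params
#' @param observer An \code{observer_params} object.
#' @param amplitude Stimulus amplitude(s), degC (0 on catch trials).
#' @return \code{detect_probability} returns the detection probability,
#'   vectorised over \code{amplitude}.
#' @export
detect_probability <- function(observer, amplitude) {
  stopifnot(inherits(observer, "observer_params"))
  a <- pmax(amplitude, 0)
  p <- ifelse(a == 0, 0,
              1 / (1 + (observer$threshold_amp / a)^observer$slope))
  observer$guess + (1 - observer$guess - observer$lapse) * p
}

#' Simulate one behavioural session
#'
#' Draws a randomized trial table from the schedule, then generates lick
#' timestamps as the union of a homogeneous Poisson baseline process and
#' stimulus-locked detection licks, and reward events at the first
#' in-window lick of each stimulus trial. Bit-reproducible given
#' \code{seed}.
#'
#' @param schedule A \code{\link{session_schedule}}.
#' @param observer An \code{\link{observer_params}}.
#' @param seed Integer seed; if NULL, the schedule's seed is used.
#' @return An object of class \code{session_log}: a list with
#'   \code{trials} (the trial table), \code{licks}, \code{rewards}
#'   (sorted timestamp vectors, seconds from session start) and
#'   \code{meta} (schedule and observer settings).
#' @export
#' @examples
#' log <- simulate_session(session_schedule(seed = 1), observer_params())
#' session_metrics(log)$dprime
simulate_session <- function(schedule, observer, seed = NULL) {
  stopifnot(inherits(schedule, "session_schedule"),
            inherits(observer, "observer_params"))
  if (is.null(seed)) seed <- schedule$seed
  sched <- schedule
  sched$seed <- seed
  trials <- generate_schedule(sched)
  span <- max(trials$onset_s) + step_duration(schedule$stimulus) +
    schedule$iti_max
  with_seed(if (is.null(seed)) NULL else child_seed(seed, "observer"), {
    n_base <- stats::rpois(1, observer$baseline_lick_rate * span)
    base_licks <- sort(stats::runif(n_base, 0, span))
    detected <- stats::runif(nrow(trials)) <
      detect_probability(observer, trials$amplitude_c)
    lat <- stats::rlnorm(sum(detected),
                         meanlog = log(observer$latency_median),
                         sdlog = observer$latency_spread)
    stim_licks <- trials$onset_s[detected] + lat
    licks <- sort(c(base_licks, stim_licks))
  })
  rewards <- vapply(which(trials$type == "stimulus"), function(i) {
    w <- licks[licks > trials$onset_s[i] &
                 licks <= trials$onset_s[i] + schedule$response_window]
    if (length(w)) w[1] else NA_real_
  }, numeric(1))
  session_log(trials, licks, rewards[!is.na(rewards)],
              meta = list(response_window = schedule$response_window,
                          pre_stim_lockout = schedule$pre_stim_lockout,
                          baseline_temp = schedule$stimulus$baseline_temp,
                          amplitude_c = step_amplitude(schedule$stimulus),
                          stimulus = schedule$stimulus,
                          seed = seed))
}

#' Construct a behavioural session log
#'
#' @param trials Data.frame with columns \code{trial_id}, \code{type},
#'   \code{onset_s}, \code{amplitude_c}; onsets strictly increasing.
#' @param licks Numeric vector of lick timestamps, seconds.
#' @param rewards Numeric vector of reward timestamps; each reward must
#'   coincide with a lick.
#' @param meta List of session metadata (response window, lockout, ...).
#' @return An object of class \code{session_log}.
#' @export
session_log <- function(trials, licks, rewards = numeric(0), meta = list()) {
  need <- c("trial_id", "type", "onset_s", "amplitude_c")
  if (!all(need %in% names(trials))) {
    stop("trials must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  if (is.unsorted(trials$onset_s, strictly = TRUE)) {
    stop("trial onsets must be strictly increasing", call. = FALSE)
  }
  if (!all(trials$type %in% c("stimulus", "catch"))) {
    stop("trial type must be 'stimulus' or 'catch'", call. = FALSE)
  }
  licks <- sort(as.numeric(licks))
  rewards <- sort(as.numeric(rewards))
  if (length(rewards) &&
      !all(vapply(rewards, function(r) any(abs(licks - r) < 1e-9),
                  logical(1)))) {
    stop("every reward must coincide with a lick", call. = FALSE)
  }
  structure(list(trials = trials, licks = licks, rewards = rewards,
                 meta = meta),
            class = "session_log")
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf(
    "<session_log> %d trials (%d stimulus / %d catch), %d licks, %d rewards\n",
    nrow(x$trials), sum(x$trials$type == "stimulus"),
    sum(x$trials$type == "catch"), length(x$licks), length(x$rewards)))
  invisible(x)
}
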