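#' Score the trials of a behavioural session
#'
#' A stimulus trial is a hit iff at least one lick falls in the half-open
#' window \code{(onset, onset + window]}; a catch trial is a false alarm
#' iff a lick falls in the equally long window after its virtual onset.
#' The window is half-open at the left so a lick exactly at onset does not
#' count (a response cannot precede the stimulus). Licks outside all
#' windows never change any outcome. Licks in the pre-onset lockout are
#' counted and flagged but do not affect scoring.
#'
#' @param log A \code{\link{session_log}}.
#' @param window Scoring window length, seconds (default 3.5).
#' @return A data.frame with one row per trial: \code{trial_id},
#'   \code{type}, \code{onset_s}, \code{amplitude_c}, \code{outcome}
#'   (hit/miss/false_alarm/correct_rejection), \code{first_lick_latency_s}
#'   (NA unless the trial had an in-window lick) and
#'   \code{n_lockout_licks}.
#' @export
score_trials <- function(log, window = 3.5) {
  stopifnot(inherits(log, "session_log"))
  if (window <= 0) stop("window must be > 0", call. = FALSE)
  trials <- log$trials
  lockout <- if (!is.null(log$meta$pre_stim_lockout)) {
    log$meta$pre_stim_lockout
  } else 0
  licks <- log$licks
  first_lat <- vapply(seq_len(nrow(trials)), function(i) {
    w <- licks[licks > trials$onset_s[i] &
                 licks <= trials$onset_s[i] + window]
    if (length(w)) w[1] - trials$onset_s[i] else NA_real_
  }, numeric(1))
  n_lock <- vapply(seq_len(nrow(trials)), function(i) {
    sum(licks > trials$onset_s[i] - lockout & licks <= trials$onset_s[i])
  }, integer(1))
  responded <- !is.na(first_lat)
  outcome <- ifelse(trials$type == "stimulus",
                    ifelse(responded, "hit", "miss"),
                    ifelse(responded, "false_alarm", "correct_rejection"))
  data.frame(trials[c("trial_id", "type", "onset_s", "amplitude_c")],
             outcome = outcome, first_lick_latency_s = first_lat,
             n_lockout_licks = n_lock, stringsAsFactors = FALSE)
}

#' Boundary correction for extreme hit / false-alarm rates
#'
#' Replaces a rate of exactly 1 by \code{1 - 1/(2N)} and a rate of exactly
#' 0 by \code{1/(2N)}, where N is the number of trials over which the rate
#' was measured; interior rates are unchanged. This keeps the inverse
#' normal transform, and hence d-prime, finite.
#'
#' @param rate Observed rate in [0, 1].
#' @param n Number of trials, >= 1.
#' @return The corrected rate.
#' @export
#' @examples
#' corrected_rate(1, 50)   # 0.99
#' corrected_rate(0, 50)   # 0.01
corrected_rate <- function(rate, n) {
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  if (any(rate < 0 | rate > 1)) stop("rate must lie in [0, 1]",
                                     call. = FALSE)
  ifelse(rate >= 1, 1 - 1 / (2 * n),
         ifelse(rate <= 0, 1 / (2 * n), rate))
}

#' Signal-detection sensitivity index d-prime
#'
#' \code{d' = z(h) - z(fa)}, where z is the inverse of the standard normal
#' cumulative distribution function, after applying the boundary
#' correction of \code{\link{corrected_rate}} to each rate with its own
#' trial count. Always finite; antisymmetric under swapping h and fa when
#' the trial counts match.
#'
#' @param h Hit rate.
#' @param fa False-alarm rate.
#' @param n_stim Number of stimulus trials.
#' @param n_catch Number of catch trials.
#' @return d-prime (dimensionless).
#' @export
#' @examples
#' dprime(0.9, 0.1, 50, 50)   # 2.5631
#' dprime(1, 0, 50, 50)       # 4.6527 = 2 * qnorm(0.99)
dprime <- function(h, fa, n_stim, n_catch = n_stim) {
  stats::qnorm(corrected_rate(h, n_stim)) -
    stats::qnorm(corrected_rate(fa, n_catch))
}

#' Summary metrics of one session
#'
#' @param log A \code{\link{session_log}}.
#' @param window Scoring window, seconds.
#' @param n_boot Bootstrap resamples for the h - fa confidence interval
#'   (trial-level resampling); 0 disables the bootstrap.
#' @param conf Confidence level.
#' @return A list with \code{n_stim}, \code{n_catch}, \code{hit_rate},
#'   \code{fa_rate}, \code{dprime}, \code{mean_first_lick_latency_s},
#'   \code{hf_diff_ci} (two-sided CI for h - fa, or NULL) and
#'   \code{outcomes} (the per-trial score table).
#' @export
session_metrics <- function(log, window = 3.5, n_boot = 10000,
                            conf = 0.95) {
  sc <- score_trials(log, window)
  stim <- sc[sc$type == "stimulus", ]
  catch <- sc[sc$type == "catch", ]
  n_stim <- nrow(stim)
  n_catch <- nrow(catch)
  h <- if (n_stim) mean(stim$outcome == "hit") else NA_real_
  fa <- if (n_catch) mean(catch$outcome == "false_alarm") else NA_real_
  ci <- if (n_boot > 0 && n_stim > 0 && n_catch > 0) {
    bootstrap_rate_difference(h, fa, n_stim, n_catch, n_boot, conf)
  } else NULL
  list(
    n_stim = n_stim, n_catch = n_catch,
    hit_rate = h, fa_rate = fa,
    dprime = if (n_stim > 0 && n_catch > 0) dprime(h, fa, n_stim, n_catch)
             else NA_real_,
    mean_first_lick_latency_s =
      if (any(stim$outcome == "hit")) {
        mean(stim$first_lick_latency_s[stim$outcome == "hit"])
      } else NA_real_,
    hf_diff_ci = ci,
    outcomes = sc
  )
}

#' Trial-level bootstrap of the hit minus false-alarm rate difference
#'
#' Resamples the binary per-trial outcomes of the stimulus and catch trial
#' sets with replacement (equivalently, binomial resampling of each rate)
#' and returns a two-sided percentile confidence interval for h - fa.
#'
#' @param h,fa Observed rates.
#' @param n_stim,n_catch Trial counts.
#' @param n_boot Number of resamples (default 10000).
#' @param conf Confidence level.
#' @return Numeric vector \code{c(lower, upper)}.
#' @export
bootstrap_rate_difference <- function(h, fa, n_stim, n_catch,
                                      n_boot = 10000, conf = 0.95) {
  diffs <- stats::rbinom(n_boot, n_stim, h) / n_stim -
    stats::rbinom(n_boot, n_catch, fa) / n_catch
  unname(stats::quantile(diffs, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
}

#' First-lick latencies of hit trials
#'
#' @param log A \code{\link{session_log}}.
#' @param window Scoring window, seconds.
#' @return Numeric vector of latencies (first in-window lick minus onset),
#'   one per hit trial; misses and catch trials contribute nothing.
#' @export
first_lick_latencies <- function(log, window = 3.5) {
  sc <- score_trials(log, window)
  sc$first_lick_latency_s[sc$type == "stimulus" & sc$outcome == "hit"]
}

#' Peri-stimulus time histogram of first licks
#'
#' Bins the first lick following each trial onset (within the analysis
#' window) relative to onset, separately for stimulus and catch trials.
#' The total count over bins equals the number of trials with an in-window
#' first lick (event conservation).
#'
#' @param logs A \code{\link{session_log}} or list of them.
#' @param bin_width Bin width, seconds.
#' @param window Analysis window \code{c(pre, post)} relative to onset,
#'   seconds; first licks are sought in \code{(onset, onset + post]}.
#' @param normalization "count", "probability" (per trial) or "rate" (Hz
#'   per trial).
#' @return A data.frame with \code{bin_start_s}, \code{bin_end_s}, and the
#'   stimulus- and catch-trial values (\code{stimulus}, \code{catch});
#'   attributes record trial counts.
#' @export
lick_psth <- function(logs, bin_width = 0.25, window = c(0, 4),
                      normalization = c("count", "probability", "rate")) {
  normalization <- match.arg(normalization)
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  if (inherits(logs, "session_log")) logs <- list(logs)
  edges <- seq(window[1], window[2], by = bin_width)
  if (edges[length(edges)] < window[2] - 1e-12) edges <- c(edges, window[2])
  mids <- utils::head(edges, -1)
  lat <- list(stimulus = numeric(0), catch = numeric(0))
  n_trials <- c(stimulus = 0, catch = 0)
  for (log in logs) {
    sc <- score_trials(log, window = window[2])
    for (ty in c("stimulus", "catch")) {
      rows <- sc[sc$type == ty, ]
      n_trials[ty] <- n_trials[ty] + nrow(rows)
      lat[[ty]] <- c(lat[[ty]],
                     rows$first_lick_latency_s[!is.na(rows$first_lick_latency_s)])
    }
  }
  binify <- function(x, n) {
    counts <- if (length(x)) {
      tabulate(findInterval(x, edges, rightmost.closed = TRUE,
                            left.open = TRUE) , nbins = length(mids))
    } else rep(0L, length(mids))
    switch(normalization,
           count = counts,
           probability = if (n > 0) counts / n else counts * 0,
           rate = if (n > 0) counts / (n * bin_width) else counts * 0)
  }
  out <- data.frame(bin_start_s = mids,
                    bin_end_s = edges[-1],
                    stimulus = binify(lat$stimulus, n_trials["stimulus"]),
                    catch = binify(lat$catch, n_trials["catch"]))
  attr(out, "n_trials") <- n_trials
  attr(out, "normalization") <- normalization
  out
}

#' Per-session learning curve
#'
#' Computes hit rate, false-alarm rate and d-prime for an ordered list of
#' sessions, with a trial-level bootstrap confidence interval for h - fa
#' in each session.
#'
#' @param logs List of \code{\link{session_log}} objects, in session
#'   order.
#' @param window Scoring window, seconds.
#' @param n_boot Bootstrap resamples per session.
#' @return A data.frame with one row per session: \code{session},
#'   \code{n_stim}, \code{n_catch}, \code{hit_rate}, \code{fa_rate},
#'   \code{dprime}, \code{hf_diff_lo}, \code{hf_diff_hi}.
#' @export
learning_curve <- function(logs, window = 3.5, n_boot = 10000) {
  if (inherits(logs, "session_log")) logs <- list(logs)
  if (length(logs) < 1) stop("need at least one session", call. = FALSE)
  rows <- lapply(seq_along(logs), function(i) {
    m <- session_metrics(logs[[i]], window = window, n_boot = n_boot)
    data.frame(session = i, n_stim = m$n_stim, n_catch = m$n_catch,
               hit_rate = m$hit_rate, fa_rate = m$fa_rate,
               dprime = m$dprime,
               hf_diff_lo = if (is.null(m$hf_diff_ci)) NA_real_
                            else m$hf_diff_ci[1],
               hf_diff_hi = if (is.null(m$hf_diff_ci)) NA_real_
                            else m$hf_diff_ci[2])
  })
  do.call(rbind, rows)
}

#' Estimate the perceptual threshold from an amplitude series
#'
#' Given per-amplitude session metrics, the threshold is the smallest
#' tested amplitude whose d-prime reaches the criterion and whose
#' bootstrap confidence interval for h - fa excludes 0. Returns NA if no
#' amplitude qualifies.
#'
#' @param series A data.frame with columns \code{amplitude_c},
#'   \code{dprime} and \code{hf_diff_lo} (lower CI bound for h - fa), as
#'   produced by \code{\link{threshold_series}}.
#' @param criterion_dprime Detection criterion on d-prime (default 1.0).
#' @return The threshold amplitude in degC, or \code{NA_real_}.
#' @export
estimate_threshold <- function(series, criterion_dprime = 1.0) {
  need <- c("amplitude_c", "dprime", "hf_diff_lo")
  if (!all(need %in% names(series)) || nrow(series) < 2) {
    stop("series needs >= 2 amplitudes with columns ",
         paste(need, collapse = ","), call. = FALSE)
  }
  ok <- series$dprime >= criterion_dprime & series$hf_diff_lo > 0
  if (!any(ok, na.rm = TRUE)) return(NA_real_)
  min(series$amplitude_c[which(ok)])
}

#' @rdname estimate_threshold
#' @param logs Named or unnamed list of session logs, one per amplitude.
#' @param amplitudes Stimulus amplitude of each session, degC.
#' @param window Scoring window, seconds.
#' @param n_boot Bootstrap resamples.
#' @return \code{threshold_series} returns the per-amplitude metrics
#'   data.frame accepted by \code{estimate_threshold}.
#' @export
threshold_series <- function(logs, amplitudes, window = 3.5,
                             n_boot = 10000) {
  stopifnot(length(logs) == length(amplitudes))
  lc <- learning_curve(logs, window = window, n_boot = n_boot)
  data.frame(amplitude_c = amplitudes, lc[, -1, drop = FALSE])
}
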