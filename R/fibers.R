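#' Spike train of a single afferent unit
#'
#' @param spike_times Numeric vector of spike timestamps, seconds; must be
#'   strictly increasing (simultaneous spikes are disallowed).
#' @param unit_id Unit identifier.
#' @param span Recording span, seconds; all spikes must lie in
#'   \code{[0, span]}.
#' @return An object of class \code{spike_train}.
#' @export
spike_train <- function(spike_times, unit_id = 1L, span = NULL) {
  spike_times <- as.numeric(spike_times)
  if (length(spike_times) && is.unsorted(spike_times, strictly = TRUE)) {
    stop("spike times must be strictly increasing", call. = FALSE)
  }
  if (is.null(span)) {
    span <- if (length(spike_times)) max(spike_times) else 0
  }
  if (length(spike_times) &&
      (spike_times[1] < 0 || spike_times[length(spike_times)] > span + 1e-9)) {
    stop("spike times must lie within [0, span]", call. = FALSE)
  }
  structure(list(unit_id = unit_id, spike_times = spike_times,
                 span = span),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> unit %s: %d spikes over %.1f s\n",
              as.character(x$unit_id), length(x$spike_times), x$span))
  invisible(x)
}

#' Thermosensitive fiber parameter sets
#'
#' Two generative fiber archetypes reproduce the thermal response types
#' seen in forepaw recordings:
#'
#' \describe{
#'   \item{warm-excited}{Polymodal fibers (C-MH, C-MHC, A-MH) silent below
#'     an absolute temperature threshold \code{t_on}, above which the rate
#'     rises linearly at \code{gain} Hz/degC up to \code{r_max}. In
#'     \code{noxious_mode = "preferring"} the rate peaks at
#'     \code{rolloff_temp} and falls with equal slope above it (fibers
#'     inhibited by noxious heat). \code{noxious_cutoff} /
#'     \code{noxious_scale} rescale the incremental gain above the cutoff
#'     temperature and implement genotype presets that blunt noxious-range
#'     acceleration.}
#'   \item{cool-driven tonic}{Fibers with ongoing activity (0.2-6 Hz at a
#'     steady background), excited by cooling at \code{cool_gain} Hz/degC
#'     and multiplicatively suppressed toward zero by warming at
#'     \code{warm_suppression_gain} per degC. The rate re-references to the
#'     session background temperature instantaneously (no adaptation time
#'     constant), matching the observation that ongoing rates are similar
#'     at 32 and 22 degC baselines. With \code{ongoing_rate = 0} the same
#'     form gives a phasic cool-excited fiber.}
#' }
#'
#' @param t_on Absolute threshold temperature, degC.
#' @param gain Supra-threshold gain, Hz/degC.
#' @param r_max Rate ceiling, Hz.
#' @param noxious_mode "monotonic" or "preferring".
#' @param rolloff_temp Peak temperature for preferring fibers, degC.
#' @param noxious_cutoff Temperature above which the incremental gain is
#'   rescaled by \code{noxious_scale} (Inf = no rescaling).
#' @param noxious_scale Gain multiplier above \code{noxious_cutoff}.
#' @param class_label Fiber class label (see \code{\link{classify_fiber}}).
#' @param cv Conduction velocity, m/s.
#' @param refractory Absolute refractory period, seconds (default 5 ms).
#' @return An object of class \code{fiber_params} with a \code{kind} field
#'   ("warm_excited" or "cool_tonic").
#' @export
#' @examples
#' f <- warm_fiber(t_on = 38, gain = 2)
#' fiber_rate(f, c(37, 40, 43), background_temp = 32)  # 0, 4, 10 Hz
warm_fiber <- function(t_on, gain = 2, r_max = 30,
                       noxious_mode = c("monotonic", "preferring"),
                       rolloff_temp = 45, noxious_cutoff = Inf,
                       noxious_scale = 1, class_label = "C-MH", cv = 0.6,
                       refractory = 0.005) {
  noxious_mode <- match.arg(noxious_mode)
  if (gain < 0 || r_max < 0 || refractory < 0) {
    stop("gain, r_max and refractory must be >= 0", call. = FALSE)
  }
  structure(
    list(kind = "warm_excited", t_on = t_on, gain = gain, r_max = r_max,
         noxious_mode = noxious_mode, rolloff_temp = rolloff_temp,
         noxious_cutoff = noxious_cutoff, noxious_scale = noxious_scale,
         class_label = class_label, cv = cv, refractory = refractory),
    class = "fiber_params"
  )
}

#' @rdname warm_fiber
#' @param ongoing_rate Ongoing rate at the adaptation/background
#'   temperature, Hz.
#' @param cool_gain Cooling gain, Hz/degC.
#' @param warm_suppression_gain Fractional suppression per degC of warming.
#' @param adaptation_temp Reference temperature at which the ongoing rate
#'   is defined; \code{NA} means "the session background temperature".
#' @export
tonic_fiber <- function(ongoing_rate, cool_gain = 1,
                        warm_suppression_gain = 0.2, adaptation_temp = NA,
                        r_max = 50, class_label = "C-MC", cv = 0.6,
                        refractory = 0.005) {
  if (ongoing_rate < 0 || cool_gain < 0 || warm_suppression_gain < 0) {
    stop("rates and gains must be >= 0", call. = FALSE)
  }
  structure(
    list(kind = "cool_tonic", ongoing_rate = ongoing_rate,
         cool_gain = cool_gain,
         warm_suppression_gain = warm_suppression_gain,
         adaptation_temp = adaptation_temp, r_max = r_max,
         class_label = class_label, cv = cv, refractory = refractory),
    class = "fiber_params"
  )
}

#' Instantaneous firing rate of a fiber at a given temperature
#'
#' @param fiber A \code{\link{warm_fiber}} or \code{\link{tonic_fiber}}.
#' @param temp Temperature(s), degC; vectorised.
#' @param background_temp Session background temperature, degC; the
#'   reference for tonic fibers whose \code{adaptation_temp} is NA.
#' @return Firing rate(s) in Hz; never negative.
#' @export
fiber_rate <- function(fiber, temp, background_temp = 32) {
  stopifnot(inherits(fiber, "fiber_params"))
  if (fiber$kind == "warm_excited") {
    warm_rate(temp, fiber$t_on, fiber$gain, fiber$r_max, fiber$noxious_mode,
              fiber$rolloff_temp, fiber$noxious_cutoff, fiber$noxious_scale)
  } else {
    ref <- if (is.na(fiber$adaptation_temp)) background_temp
           else fiber$adaptation_temp
    tonic_rate(temp, ref, fiber$ongoing_rate, fiber$cool_gain,
               fiber$warm_suppression_gain, fiber$r_max)
  }
}

# Vectorised rate kernels shared by fiber_rate and the population model.
warm_rate <- function(temp, t_on, gain, r_max, noxious_mode, rolloff_temp,
                      noxious_cutoff, noxious_scale) {
  if (identical(noxious_mode, "preferring")) {
    drive <- pmax(pmin(temp, rolloff_temp) - t_on, 0) -
      pmax(temp - rolloff_temp, 0)
  } else {
    drive <- pmax(pmin(temp, noxious_cutoff) - t_on, 0) +
      noxious_scale * pmax(temp - pmax(noxious_cutoff, t_on), 0)
  }
  pmin(pmax(gain * drive, 0), r_max)
}

tonic_rate <- function(temp, ref, ongoing_rate, cool_gain,
                       warm_suppression_gain, r_max) {
  dwarm <- pmax(temp - ref, 0)
  dcool <- pmax(ref - temp, 0)
  r <- ongoing_rate * pmax(1 - warm_suppression_gain * dwarm, 0) +
    cool_gain * dcool
  pmin(r, r_max)
}

#' Simulate a fiber's spike train under a temperature trace
#'
#' Inhomogeneous Poisson process realised by thinning, followed by
#' enforcement of an absolute refractory period: after each accepted
#' spike, candidates closer than \code{refractory} are discarded. When the
#' refractory period is much shorter than the mean inter-spike interval,
#' the expected spike count equals the integral of the instantaneous rate
#' over the trace.
#'
#' @param fiber A \code{\link{fiber_params}}.
#' @param trace A \code{\link{temperature_trace}}.
#' @param background_temp Session background temperature, degC.
#' @param seed Integer seed or NULL.
#' @param unit_id Identifier stored in the returned train.
#' @return A \code{\link{spike_train}} spanning the trace.
#' @export
simulate_fiber <- function(fiber, trace, background_temp = 32, seed = NULL,
                           unit_id = 1L) {
  stopifnot(inherits(fiber, "fiber_params"),
            inherits(trace, "temperature_trace"))
  t0 <- trace$time_s[1]
  t1 <- trace$time_s[length(trace$time_s)]
  span <- t1 - t0
  rate_fn <- function(t) fiber_rate(fiber, temperature_at(trace, t),
                                    background_temp)
  rmax <- max(fiber_rate(fiber, trace$temp_c, background_temp))
  spikes <- with_seed(seed, {
    if (rmax <= 0) {
      numeric(0)
    } else {
      n_cand <- stats::rpois(1, rmax * span)
      cand <- sort(stats::runif(n_cand, t0, t1))
      keep <- cand[stats::runif(n_cand) < rate_fn(cand) / rmax]
      apply_refractory(keep, fiber$refractory)
    }
  })
  spike_train(spikes - t0, unit_id = unit_id, span = span)
}

# Drop spikes arriving within `refractory` of the previous accepted spike.
apply_refractory <- function(times, refractory) {
  if (length(times) < 2L || refractory <= 0) return(times)
  out <- numeric(length(times))
  out[1] <- times[1]
  k <- 1L
  for (t in times[-1]) {
    if (t - out[k] >= refractory) {
      k <- k + 1L
      out[k] <- t
    }
  }
  out[seq_len(k)]
}
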