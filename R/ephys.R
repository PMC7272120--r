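#' Conduction velocity from electrical-search latency
#'
#' @param distance_m Conduction distance, meters.
#' @param latency_s Response latency to electrical stimulation of the
#'   receptive field, seconds.
#' @return Conduction velocity in m/s.
#' @export
conduction_velocity <- function(distance_m, latency_s) {
  if (any(distance_m <= 0) || any(latency_s <= 0)) {
    stop("distance and latency must be > 0", call. = FALSE)
  }
  distance_m / latency_s
}

#' Classify an afferent unit by conduction velocity and modality
#'
#' Velocity assigns the prefix: C for cv < 1.2 m/s, A (A-delta) for
#' 1.2 <= cv <= 10 m/s (both boundary values read as A-delta), and A-beta
#' above 10 m/s (outside the thermosensory scheme). The suffix joins the
#' responsive modalities in M, H, C order: mech+heat -> MH,
#' mech+heat+cold -> MHC, mech+cold -> MC, cold only -> C (as in C-C).
#' Heat-only units without mechanosensitivity (not observed in the
#' recorded sample) are labelled -H for totality; mech-only units -M. A
#' unit with no responsive modality is "non-thermosensory".
#'
#' @param cv Conduction velocity, m/s.
#' @param responds_mech,responds_heat,responds_cold Modality flags.
#' @return A class label string; vectorised over inputs.
#' @export
#' @examples
#' classify_fiber(0.5, TRUE, TRUE, FALSE)   # "C-MH"
#' classify_fiber(0.5, FALSE, FALSE, TRUE)  # "C-C"
#' classify_fiber(5, TRUE, TRUE, FALSE)     # "A-MH"
classify_fiber <- function(cv, responds_mech, responds_heat,
                           responds_cold) {
  n <- max(length(cv), length(responds_mech), length(responds_heat),
           length(responds_cold))
  cv <- rep_len(cv, n)
  m <- rep_len(responds_mech, n)
  h <- rep_len(responds_heat, n)
  cd <- rep_len(responds_cold, n)
  if (any(!is.finite(cv)) || any(cv <= 0)) {
    stop("conduction velocity must be finite and > 0", call. = FALSE)
  }
  prefix <- ifelse(cv < 1.2, "C", ifelse(cv <= 10, "A", "A-beta"))
  suffix <- paste0(ifelse(m, "M", ""), ifelse(h, "H", ""),
                   ifelse(cd, "C", ""))
  out <- ifelse(suffix == "", "non-thermosensory",
                ifelse(prefix == "A-beta", "A-beta",
                       paste0(prefix, "-", suffix)))
  out
}

#' Thermal threshold from the first stimulus-evoked spike
#'
#' The threshold is the temperature of the stimulus trace at the time of
#' the unit's first spike within the stimulus epoch (the temperature
#' required to elicit the first action potential).
#'
#' @param train A \code{\link{spike_train}} whose time base matches the
#'   trace (t = 0 at trace start).
#' @param trace A \code{\link{temperature_trace}} spanning the train.
#' @param epoch Optional \code{c(start, end)} restricting the search,
#'   seconds; default the whole trace.
#' @return Threshold temperature in degC, or \code{NA_real_} if the unit
#'   fired no spikes in the epoch.
#' @export
thermal_threshold <- function(train, trace, epoch = NULL) {
  stopifnot(inherits(train, "spike_train"),
            inherits(trace, "temperature_trace"))
  span <- trace$time_s[length(trace$time_s)] - trace$time_s[1]
  if (train$span > span + 1e-9) {
    stop("spike train span exceeds the temperature trace span",
         call. = FALSE)
  }
  st <- train$spike_times
  if (!is.null(epoch)) st <- st[st >= epoch[1] & st <= epoch[2]]
  if (!length(st)) return(NA_real_)
  temperature_at(trace, trace$time_s[1] + st[1])
}

#' Is a unit responsive to non-noxious temperatures?
#'
#' Non-noxious responsiveness is defined as spiking to stimuli below 42
#' degC for warming or above 22 degC for cooling.
#'
#' @param warm_threshold Warm threshold, degC, or NA if absent.
#' @param cold_threshold Cold threshold, degC, or NA if absent.
#' @return Logical flag.
#' @export
is_nonnoxious_responsive <- function(warm_threshold = NA,
                                     cold_threshold = NA) {
  if (is.na(warm_threshold) && is.na(cold_threshold)) {
    stop("at least one thermal threshold must be present", call. = FALSE)
  }
  isTRUE(warm_threshold < 42) || isTRUE(cold_threshold > 22)
}

#' Ongoing activity of a unit in a stimulus-free baseline window
#'
#' The ongoing rate is the spike count divided by the window duration. A
#' unit is flagged as having ongoing activity when its rate reaches the
#' floor (default 0.1 Hz, below the observed 0.2-6 Hz range) sustained in
#' both halves of the window.
#'
#' @param train A \code{\link{spike_train}}.
#' @param baseline_window \code{c(start, end)} in seconds; must be free of
#'   applied stimuli. Windows shorter than 10 s trigger a warning but are
#'   still computed.
#' @param floor Detection floor, Hz.
#' @return A list with \code{rate} (Hz) and \code{is_ongoing}.
#' @export
ongoing_activity <- function(train, baseline_window, floor = 0.1) {
  stopifnot(inherits(train, "spike_train"), length(baseline_window) == 2)
  dur <- diff(baseline_window)
  if (dur <= 0) stop("baseline window must have positive length",
                     call. = FALSE)
  if (dur < 10) warning("baseline window shorter than 10 s; ongoing-rate ",
                        "estimate will be noisy")
  st <- train$spike_times
  mid <- baseline_window[1] + dur / 2
  n1 <- sum(st > baseline_window[1] & st <= mid)
  n2 <- sum(st > mid & st <= baseline_window[2])
  rate <- (n1 + n2) / dur
  list(rate = rate,
       is_ongoing = rate >= floor &&
         n1 / (dur / 2) >= floor && n2 / (dur / 2) >= floor)
}

#' Percentage firing-rate change between baseline and stimulus windows
#'
#' \code{100 * (stim_rate - baseline_rate) / baseline_rate}. Complete
#' silencing gives -100. Undefined (NA) when the baseline rate is zero.
#'
#' @param train A \code{\link{spike_train}}.
#' @param baseline_window,stim_window Non-overlapping \code{c(start, end)}
#'   windows, seconds.
#' @return Percentage change, or \code{NA_real_} if the baseline rate is
#'   zero.
#' @export
rate_change_index <- function(train, baseline_window, stim_window) {
  stopifnot(inherits(train, "spike_train"))
  if (max(baseline_window[1], stim_window[1]) <
      min(baseline_window[2], stim_window[2])) {
    stop("baseline and stimulus windows must not overlap", call. = FALSE)
  }
  count_in <- function(w) sum(train$spike_times > w[1] &
                                train$spike_times <= w[2])
  base <- count_in(baseline_window) / diff(baseline_window)
  stim <- count_in(stim_window) / diff(stim_window)
  if (base <= 0) return(NA_real_)
  100 * (stim - base) / base
}

#' Peri-stimulus time histogram of spike rate
#'
#' Pools spikes from a set of units over a set of stimulus repeats and
#' returns the mean rate per bin: pooled count / (repeats x units x bin
#' width). The conservation identity
#' \code{sum(rate * bin_width) * repeats * units = total in-window spikes}
#' holds exactly.
#'
#' @param trains List of \code{\link{spike_train}} objects (or a single
#'   one); spike times on the session time base.
#' @param onsets Stimulus onset times, seconds (one per repeat).
#' @param bin_width Bin width, seconds.
#' @param window Analysis window \code{c(pre, post)} relative to onset.
#' @return A data.frame with \code{bin_start_s}, \code{bin_end_s},
#'   \code{count} (pooled) and \code{rate_hz}; attributes \code{n_trials}
#'   and \code{n_units}.
#' @export
spike_psth <- function(trains, onsets, bin_width = 0.25,
                       window = c(-1, 4)) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  stopifnot(length(onsets) >= 1, bin_width > 0)
  edges <- seq(window[1], window[2], by = bin_width)
  if (edges[length(edges)] < window[2] - 1e-12) edges <- c(edges, window[2])
  nb <- length(edges) - 1L
  counts <- rep(0L, nb)
  for (tr in trains) {
    for (on in onsets) {
      rel <- tr$spike_times - on
      rel <- rel[rel > window[1] & rel <= window[2]]
      if (length(rel)) {
        counts <- counts + tabulate(
          findInterval(rel, edges, rightmost.closed = TRUE,
                       left.open = TRUE), nbins = nb)
      }
    }
  }
  widths <- diff(edges)
  out <- data.frame(bin_start_s = utils::head(edges, -1),
                    bin_end_s = edges[-1],
                    count = counts,
                    rate_hz = counts /
                      (length(onsets) * length(trains) * widths))
  attr(out, "n_trials") <- length(onsets)
  attr(out, "n_units") <- length(trains)
  out
}

#' Classify a thermal tuning curve as monotonic or range-preferring
#'
#' Given mean rates sampled on an increasing temperature grid, a unit is
#' "preferring" iff its peak rate occurs at least 2 degC before the grid
#' maximum and its terminal rate is at most half the peak; otherwise
#' "monotonic". A flat all-zero curve is monotonic (degenerate) and
#' flagged non-responsive via the \code{"responsive"} attribute.
#'
#' @param temps Increasing temperature grid, degC; length >= 3.
#' @param rates Mean rates at those temperatures, Hz.
#' @return "monotonic" or "preferring", with attribute
#'   \code{responsive}.
#' @export
monotonicity_class <- function(temps, rates) {
  if (length(temps) < 3 || length(rates) != length(temps)) {
    stop("need >= 3 grid points with matching rates", call. = FALSE)
  }
  if (is.unsorted(temps, strictly = TRUE)) {
    stop("temperature grid must be increasing", call. = FALSE)
  }
  if (all(rates == 0)) {
    return(structure("monotonic", responsive = FALSE))
  }
  peak <- which.max(rates)
  preferring <- temps[peak] <= max(temps) - 2 &&
    rates[length(rates)] <= 0.5 * rates[peak]
  structure(if (preferring) "preferring" else "monotonic",
            responsive = TRUE)
}
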