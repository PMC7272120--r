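#' Parameters of a ramp-hold-ramp thermal step stimulus
#'
#' The standard warm/cool step used in the behavioural task: a linear ramp
#' from baseline to target, a hold at target, and a linear return ramp.
#' Defaults are the behavioural stimulus (32 to 42 degC, 0.5 s ramp,
#' 3 s hold, 0.5 s return; total 4 s).
#'
#' @param baseline_temp Baseline temperature, degC.
#' @param target_temp Plateau temperature, degC.
#' @param ramp_up_dur,hold_dur,ramp_down_dur Segment durations, seconds;
#'   all must be >= 0.
#' @return An object of class \code{step_waveform_params}.
#' @export
#' @examples
#' step_waveform_params()                       # 32 -> 42 degC, 4 s
#' step_waveform_params(target_temp = 33)       # a 1 degC threshold step
step_waveform_params <- function(baseline_temp = 32, target_temp = 42,
                                 ramp_up_dur = 0.5, hold_dur = 3,
                                 ramp_down_dur = 0.5) {
  durs <- c(ramp_up_dur, hold_dur, ramp_down_dur)
  if (any(!is.finite(durs)) || any(durs < 0)) {
    stop("segment durations must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(baseline_temp) || !is.finite(target_temp)) {
    stop("temperatures must be finite", call. = FALSE)
  }
  structure(
    list(baseline_temp = baseline_temp, target_temp = target_temp,
         ramp_up_dur = ramp_up_dur, hold_dur = hold_dur,
         ramp_down_dur = ramp_down_dur),
    class = "step_waveform_params"
  )
}

#' @rdname step_waveform_params
#' @param params A \code{step_waveform_params} object.
#' @export
step_duration <- function(params) {
  params$ramp_up_dur + params$hold_dur + params$ramp_down_dur
}

#' @rdname step_waveform_params
#' @export
step_amplitude <- function(params) {
  params$target_temp - params$baseline_temp
}

#' Parameters of a constant-rate linear thermal ramp
#'
#' Long search ramps, e.g. 32 to 48 degC at 1 degC/s (heat) or 32 to 12 degC
#' at 1 degC/s (cold).
#'
#' @param start_temp,end_temp Endpoint temperatures, degC.
#' @param rate Absolute ramp speed, degC/s; must be > 0.
#' @return An object of class \code{ramp_params} with a \code{duration}
#'   field equal to \code{abs(end_temp - start_temp) / rate}.
#' @export
ramp_params <- function(start_temp, end_temp, rate = 1) {
  if (!is.finite(rate) || rate <= 0) {
    stop("ramp rate must be > 0", call. = FALSE)
  }
  structure(
    list(start_temp = start_temp, end_temp = end_temp, rate = rate,
         duration = abs(end_temp - start_temp) / rate),
    class = "ramp_params"
  )
}

#' Construct a temperature trace
#'
#' A trace is the package-wide representation of a time-ordered temperature
#' signal: strictly increasing sample times (seconds) and matched
#' temperatures (degC). These are command temperatures; skin-temperature
#' lag is not modelled.
#'
#' @param time_s Numeric vector of sample times, strictly increasing,
#'   length >= 2.
#' @param temp_c Numeric vector of temperatures, same length.
#' @return An object of class \code{temperature_trace}.
#' @export
temperature_trace <- function(time_s, temp_c) {
  if (length(time_s) < 2L || length(time_s) != length(temp_c)) {
    stop("trace needs >= 2 samples with matching times and temperatures",
         call. = FALSE)
  }
  if (any(!is.finite(time_s)) || any(!is.finite(temp_c))) {
    stop("trace samples must be finite", call. = FALSE)
  }
  if (any(diff(time_s) <= 0)) {
    stop("trace sample times must be strictly increasing", call. = FALSE)
  }
  structure(
    list(time_s = as.numeric(time_s), temp_c = as.numeric(temp_c),
         sample_rate = (length(time_s) - 1) / (time_s[length(time_s)] - time_s[1])),
    class = "temperature_trace"
  )
}

#' @export
print.temperature_trace <- function(x, ...) {
  cat(sprintf("<temperature_trace> %d samples over %.3f s, %.1f-%.1f degC\n",
              length(x$time_s), x$time_s[length(x$time_s)] - x$time_s[1],
              min(x$temp_c), max(x$temp_c)))
  invisible(x)
}

# Time grid spanning [0, total] at sample_rate, endpoint always included.
time_grid <- function(total, sample_rate) {
  n <- floor(total * sample_rate + 1e-9)
  t <- (0:n) / sample_rate
  if (t[length(t)] < total - 1e-12) t <- c(t, total)
  t[length(t)] <- total # guard rounding so the span is exact
  t
}

#' Build a ramp-hold-ramp step waveform as a temperature trace
#'
#' @param params A \code{\link{step_waveform_params}} object.
#' @param sample_rate Sampling rate in Hz (default 1000, the behavioural
#'   acquisition rate).
#' @return A \code{\link{temperature_trace}} spanning exactly
#'   \code{ramp_up_dur + hold_dur + ramp_down_dur} seconds.
#' @export
#' @examples
#' tr <- make_step_waveform(step_waveform_params())
#' max(tr$time_s)               # 4 s
#' temperature_at(tr, 0.25)     # 37 degC, midway up the ramp
make_step_waveform <- function(params, sample_rate = 1000) {
  stopifnot(inherits(params, "step_waveform_params"))
  if (!is.finite(sample_rate) || sample_rate <= 0) {
    stop("sample_rate must be > 0", call. = FALSE)
  }
  total <- step_duration(params)
  if (total <= 0) {
    # degenerate zero-length stimulus: two coincident-in-value samples
    return(temperature_trace(c(0, 1 / sample_rate),
                             rep(params$baseline_temp, 2L)))
  }
  t <- time_grid(total, sample_rate)
  temperature_trace(t, step_temperature(params, t))
}

# Closed-form piecewise-linear temperature of a step waveform (vectorised).
step_temperature <- function(params, t) {
  b <- params$baseline_temp
  a <- params$target_temp
  t1 <- params$ramp_up_dur
  t2 <- t1 + params$hold_dur
  t3 <- t2 + params$ramp_down_dur
  out <- rep(b, length(t))
  if (t1 > 0) {
    i <- t >= 0 & t < t1
    out[i] <- b + (a - b) * t[i] / t1
  }
  i <- t >= t1 & t <= t2
  out[i] <- a
  if (params$ramp_down_dur > 0) {
    i <- t > t2 & t <= t3
    out[i] <- a + (b - a) * (t[i] - t2) / params$ramp_down_dur
  }
  out
}

#' Build a constant-rate linear ramp as a temperature trace
#'
#' @param params A \code{\link{ramp_params}} object.
#' @param sample_rate Sampling rate in Hz.
#' @return A monotone \code{\link{temperature_trace}} of duration
#'   \code{abs(end - start) / rate}.
#' @export
#' @examples
#' tr <- make_linear_ramp(ramp_params(32, 48, 1))  # 16 s heat search ramp
make_linear_ramp <- function(params, sample_rate = 1000) {
  stopifnot(inherits(params, "ramp_params"))
  if (!is.finite(sample_rate) || sample_rate <= 0) {
    stop("sample_rate must be > 0", call. = FALSE)
  }
  total <- params$duration
  if (total <= 0) {
    return(temperature_trace(c(0, 1 / sample_rate),
                             rep(params$start_temp, 2L)))
  }
  t <- time_grid(total, sample_rate)
  temp <- params$start_temp +
    (params$end_temp - params$start_temp) * t / total
  temperature_trace(t, temp)
}

#' Interpolate a temperature trace at arbitrary times
#'
#' Linear interpolation between stored samples. Querying outside the trace
#' span is an error (no extrapolation).
#'
#' @param trace A \code{\link{temperature_trace}}.
#' @param t Numeric vector of query times, seconds.
#' @return Temperatures in degC, same length as \code{t}.
#' @export
temperature_at <- function(trace, t) {
  stopifnot(inherits(trace, "temperature_trace"))
  lo <- trace$time_s[1]
  hi <- trace$time_s[length(trace$time_s)]
  eps <- 1e-9
  if (any(t < lo - eps | t > hi + eps)) {
    stop(sprintf("query time outside trace span [%.6g, %.6g]", lo, hi),
         call. = FALSE)
  }
  stats::approx(trace$time_s, trace$temp_c, xout = pmin(pmax(t, lo), hi),
                method = "linear", ties = "ordered")$y
}

#' Read and write temperature traces as CSV
#'
#' The on-disk format is a comma-separated UTF-8 file with header columns
#' \code{time_s,temp_c}. Round trips are lossless to at least 1e-6.
#'
#' @param path File path.
#' @param trace A \code{\link{temperature_trace}}.
#' @return \code{read_trace} returns a \code{temperature_trace};
#'   \code{write_trace} returns \code{path} invisibly.
#' @export
read_trace <- function(path) {
  df <- tryCatch(utils::read.csv(path, colClasses = "numeric"),
                 error = function(e) stop("malformed trace file: ",
                                          conditionMessage(e), call. = FALSE))
  if (!all(c("time_s", "temp_c") %in% names(df))) {
    stop("trace file must have columns time_s,temp_c", call. = FALSE)
  }
  if (nrow(df) < 2L) stop("trace file must contain >= 2 samples",
                          call. = FALSE)
  if (any(diff(df$time_s) <= 0)) {
    stop("trace file times must be strictly increasing", call. = FALSE)
  }
  temperature_trace(df$time_s, df$temp_c)
}

#' @rdname read_trace
#' @export
write_trace <- function(path, trace) {
  stopifnot(inherits(trace, "temperature_trace"))
  utils::write.csv(
    data.frame(time_s = trace$time_s, temp_c = trace$temp_c),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
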