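#' Decoder parameters for the dual-channel population code
#'
#' The decoder pools spikes over two afferent channels in a decision
#' window after stimulus onset: pool A, warm-excited fibers that are
#' silent at rest, and pool B, tonically active cool-driven fibers whose
#' ongoing firing is suppressed by warming. Excitation evidence is
#' \code{e = pool_a_count - pool_a_baseline}; suppression evidence is
#' \code{s = pool_b_baseline - pool_b_count}.
#'
#' Two combination rules are provided. \code{"sum"} adds the raw
#' evidence, \code{e + s}: any single channel suffices. \code{"coincidence"}
#' (the default) takes \code{min(e/sd_e, s/sd_s)} after normalising each
#' channel by its null-epoch standard deviation: concurrent excitation
#' and suppression are both required, which is what makes warm
#' unambiguous and is why removing the tonic pool abolishes detection
#' under this rule. The combination rule downstream of the afferents is
#' not known; both rules are exposed as competing operationalizations.
#'
#' @param mode "coincidence" or "sum".
#' @param criterion Decision threshold on the statistic. \code{NULL}
#'   (default) places the criterion at the 95th percentile of the null
#'   (catch-epoch) statistic distribution estimated within the same run,
#'   i.e. an ideal observer holding its false-alarm rate near 5 percent.
#' @param window Decision window after stimulus onset, seconds (default
#'   1.0, bracketing the behavioural response latencies of ~0.3-0.9 s).
#' @param z_crit Per-channel evidence criterion (in null-SD units) used
#'   by \code{\link{discriminate_warm_cool}}.
#' @return An object of class \code{decoder_params}.
#' @export
decoder_params <- function(mode = c("coincidence", "sum"),
                           criterion = NULL, window = 1.0,
                           z_crit = 1.64) {
  mode <- match.arg(mode)
  if (window <= 0) stop("decision window must be > 0", call. = FALSE)
  structure(list(mode = mode, criterion = criterion, window = window,
                 z_crit = z_crit),
            class = "decoder_params")
}

#' Channel readout: pooled spike counts in decision and baseline windows
#'
#' @param pool_a_count,pool_a_baseline Pooled warm-excited (pool A) spike
#'   counts in the decision window and in a matched pre-stimulus window.
#' @param pool_b_count,pool_b_baseline The same for the tonic cool-driven
#'   pool (pool B).
#' @param window Window length, seconds.
#' @param n_a,n_b Number of fibers contributing to each pool.
#' @return An object of class \code{channel_readout}; the count fields
#'   may be equal-length vectors (one element per trial).
#' @export
channel_readout <- function(pool_a_count, pool_a_baseline, pool_b_count,
                            pool_b_baseline, window = 1.0, n_a = NA,
                            n_b = NA) {
  counts <- cbind(pool_a_count, pool_a_baseline, pool_b_count,
                  pool_b_baseline)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  structure(list(pool_a_count = pool_a_count,
                 pool_a_baseline = pool_a_baseline,
                 pool_b_count = pool_b_count,
                 pool_b_baseline = pool_b_baseline,
                 window = window, n_a = n_a, n_b = n_b),
            class = "channel_readout")
}

#' Read out both channels from recorded/simulated spike trains
#'
#' Pools spike counts per channel in \code{(onset, onset + window]} and
#' the matched baseline window \code{(onset - window, onset]}. The tonic
#' pool (B) is identified from ongoing activity in a stimulus-free
#' baseline epoch (\code{\link{ongoing_activity}}); the warm-excited pool
#' (A) is the heat-responsive units outside pool B.
#'
#' @param trains List of \code{\link{spike_train}} objects on the session
#'   time base.
#' @param units Unit-record data.frame aligned with \code{trains} (as from
#'   \code{\link{sample_population_units}}); needs columns
#'   \code{responds_heat} and, if present, \code{is_ongoing}.
#' @param onset Stimulus onset, seconds.
#' @param window Window length, seconds.
#' @param ongoing_epoch Optional stimulus-free \code{c(start, end)} used
#'   to identify ongoing activity when \code{units$is_ongoing} is absent.
#' @return A \code{\link{channel_readout}}. With no units an empty
#'   readout (all counts 0, pool sizes 0) is returned with a warning.
#' @export
population_readout <- function(trains, units, onset, window = 1.0,
                               ongoing_epoch = NULL) {
  if (length(trains) == 0) {
    warning("no units: empty readout")
    return(channel_readout(0, 0, 0, 0, window, n_a = 0, n_b = 0))
  }
  stopifnot(length(trains) == nrow(units))
  in_b <- if (!is.null(units$is_ongoing) && is.null(ongoing_epoch)) {
    units$is_ongoing
  } else {
    if (is.null(ongoing_epoch)) {
      stop("need units$is_ongoing or an ongoing_epoch", call. = FALSE)
    }
    vapply(trains, function(tr)
      ongoing_activity(tr, ongoing_epoch)$is_ongoing, logical(1))
  }
  in_a <- units$responds_heat & !in_b
  count_pool <- function(idx, lo, hi) {
    if (!any(idx)) return(0)
    sum(vapply(trains[idx], function(tr)
      sum(tr$spike_times > lo & tr$spike_times <= hi), numeric(1)))
  }
  channel_readout(
    pool_a_count = count_pool(in_a, onset, onset + window),
    pool_a_baseline = count_pool(in_a, onset - window, onset),
    pool_b_count = count_pool(in_b, onset, onset + window),
    pool_b_baseline = count_pool(in_b, onset - window, onset),
    window = window, n_a = sum(in_a), n_b = sum(in_b)
  )
}

#' Decision statistic of the dual-channel decoder
#'
#' @param readout A \code{\link{channel_readout}} (count fields may be
#'   per-trial vectors).
#' @param decoder A \code{\link{decoder_params}}.
#' @param null_sd Optional named vector \code{c(a=, b=)} of null-epoch
#'   standard deviations of each channel's evidence, used for variance
#'   normalisation in coincidence mode. When missing, a Poisson estimate
#'   \code{sqrt(2 * mean(baseline count))} is used. SDs are floored at 1
#'   count so a silent channel yields zero, not undefined, evidence.
#' @return The decision statistic, one value per trial. Deterministic in
#'   its inputs.
#' @export
decision_statistic <- function(readout, decoder = decoder_params(),
                               null_sd = NULL) {
  stopifnot(inherits(readout, "channel_readout"),
            inherits(decoder, "decoder_params"))
  e <- readout$pool_a_count - readout$pool_a_baseline
  s <- readout$pool_b_baseline - readout$pool_b_count
  if (decoder$mode == "sum") return(e + s)
  if (is.null(null_sd)) {
    null_sd <- c(a = sqrt(2 * mean(readout$pool_a_baseline)),
                 b = sqrt(2 * mean(readout$pool_b_baseline)))
  }
  sd_a <- max(null_sd[["a"]], 1)
  sd_b <- max(null_sd[["b"]], 1)
  pmin(e / sd_a, s / sd_b)
}

#' Label a readout as warm, cool or neither
#'
#' Warm is reported iff both channels carry concurrent evidence in the
#' warm direction (normalised excitation and suppression both exceed
#' \code{z_crit}): only warming simultaneously excites pool A and
#' suppresses pool B. Cool is reported iff pool B fires significantly
#' above baseline while pool A stays silent. Anything else is "none".
#'
#' @inheritParams decision_statistic
#' @return Character vector of labels ("warm", "cool", "none"), one per
#'   trial.
#' @export
discriminate_warm_cool <- function(readout, decoder = decoder_params(),
                                   null_sd = NULL) {
  stopifnot(inherits(readout, "channel_readout"))
  if (is.null(null_sd)) {
    null_sd <- c(a = sqrt(2 * mean(readout$pool_a_baseline)),
                 b = sqrt(2 * mean(readout$pool_b_baseline)))
  }
  sd_a <- max(null_sd[["a"]], 1)
  sd_b <- max(null_sd[["b"]], 1)
  e_z <- (readout$pool_a_count - readout$pool_a_baseline) / sd_a
  s_z <- (readout$pool_b_baseline - readout$pool_b_count) / sd_b
  zc <- decoder$z_crit
  ifelse(e_z > zc & s_z > zc, "warm",
         ifelse(-s_z > zc & e_z <= zc, "cool", "none"))
}

#' Expected pooled channel intensities under a stimulus
#'
#' Integrates each fiber's instantaneous rate over the decision window of
#' the stimulus trace (trapezoidal rule on the trace grid) and over a
#' matched constant-baseline window, pooled by channel. These are the
#' Poisson means of the pooled counts; they scale additively with the
#' number of fibers, so doubling the stimulated area doubles the expected
#' pooled counts.
#'
#' @param units Unit-record data.frame.
#' @param trace Stimulus \code{\link{temperature_trace}} (t = 0 at
#'   stimulus onset).
#' @param background_temp Baseline/background temperature, degC.
#' @param window Decision window, seconds.
#' @return A list with \code{a_stim}, \code{a_base}, \code{b_stim},
#'   \code{b_base} (expected counts) and pool sizes \code{n_a},
#'   \code{n_b}.
#' @export
channel_intensities <- function(units, trace, background_temp,
                                window = 1.0) {
  stopifnot(inherits(trace, "temperature_trace"))
  keep <- trace$time_s <= trace$time_s[1] + window + 1e-9
  t <- trace$time_s[keep]
  temps <- trace$temp_c[keep]
  if (t[length(t)] < trace$time_s[1] + window - 1e-9) {
    # stimulus shorter than the window: pad at baseline
    t <- c(t, trace$time_s[1] + window)
    temps <- c(temps, background_temp)
  }
  in_b <- units$is_ongoing
  in_a <- units$kind == "warm_excited" & !in_b
  trapz <- function(y) sum((y[-1] + y[-length(y)]) / 2 * diff(t))
  pool_lambda <- function(idx) {
    if (!any(idx)) return(list(stim = 0, base = 0))
    r <- unit_rate_matrix(units[idx, , drop = FALSE], temps,
                          background_temp)
    base_r <- unit_rate_matrix(units[idx, , drop = FALSE],
                               background_temp, background_temp)
    list(stim = sum(apply(r, 2, trapz)), base = sum(base_r) * window)
  }
  a <- pool_lambda(in_a)
  b <- pool_lambda(in_b)
  list(a_stim = a$stim, a_base = a$base, b_stim = b$stim,
       b_base = b$base, n_a = sum(in_a), n_b = sum(in_b))
}

#' Simulate per-trial pooled channel counts
#'
#' Fiber identities are fixed; trial-to-trial variability comes from the
#' point process alone, so pooled counts are Poisson with the channel
#' intensities as means (the sum of independent Poisson fiber counts).
#'
#' @param intens Output of \code{\link{channel_intensities}}.
#' @param n_trials Number of trials.
#' @param seed Integer seed or NULL.
#' @param null Logical; if TRUE the decision window also sits at baseline
#'   (a catch epoch).
#' @param window Window length recorded in the readout.
#' @return A \code{\link{channel_readout}} with per-trial count vectors.
#' @export
simulate_count_readouts <- function(intens, n_trials, seed = NULL,
                                    null = FALSE, window = 1.0) {
  with_seed(seed, channel_readout(
    pool_a_count = stats::rpois(n_trials,
                                if (null) intens$a_base else intens$a_stim),
    pool_a_baseline = stats::rpois(n_trials, intens$a_base),
    pool_b_count = stats::rpois(n_trials,
                                if (null) intens$b_base else intens$b_stim),
    pool_b_baseline = stats::rpois(n_trials, intens$b_base),
    window = window, n_a = intens$n_a, n_b = intens$n_b
  ))
}

#' Predicted detection sensitivity of the population code
#'
#' Simulates \code{n_trials} stimulus epochs and \code{n_trials} null
#' (catch) epochs of the pooled dual-channel readout, computes the
#' decision statistic for each, and reports two sensitivity measures:
#' \code{predicted_dprime}, the behavioural-style d-prime obtained by
#' thresholding the statistic at the decoder criterion and applying
#' \code{\link{dprime}} to the resulting hit and false-alarm rates; and
#' \code{dprime_gaussian}, the distribution-based index
#' \code{(mean_stim - mean_null) / pooled SD}. Degenerate zero-variance
#' statistic distributions are flagged and give a Gaussian index of 0.
#'
#' @param spec A \code{\link{population_spec}} (its genotype preset is
#'   already applied).
#' @param stimulus A \code{\link{step_waveform_params}} or a
#'   \code{\link{temperature_trace}} starting at stimulus onset.
#' @param decoder A \code{\link{decoder_params}}.
#' @param n_trials Trials per condition (>= 100).
#' @param background_temp Background temperature, degC; defaults to the
#'   stimulus baseline.
#' @param seed Integer seed.
#' @return An object of class \code{model_result}: a list with the
#'   condition descriptors, \code{predicted_dprime},
#'   \code{dprime_gaussian}, \code{hit_rate}, \code{fa_rate},
#'   \code{criterion}, pool sizes, the per-trial statistics and the
#'   per-trial warm/cool/none labels of the stimulus epochs.
#' @export
#' @examples
#' spec <- population_spec(seed = 1)
#' res <- model_dprime(spec, step_waveform_params(), n_trials = 100,
#'                     seed = 1)
#' res$predicted_dprime
model_dprime <- function(spec, stimulus, decoder = decoder_params(),
                         n_trials = 200, background_temp = NULL,
                         seed = 1) {
  stopifnot(inherits(spec, "population_spec"),
            inherits(decoder, "decoder_params"))
  if (n_trials < 100) stop("n_trials must be >= 100", call. = FALSE)
  if (inherits(stimulus, "step_waveform_params")) {
    trace <- make_step_waveform(stimulus, sample_rate = 200)
    if (is.null(background_temp)) background_temp <- stimulus$baseline_temp
    amplitude <- step_amplitude(stimulus)
  } else {
    stopifnot(inherits(stimulus, "temperature_trace"))
    trace <- stimulus
    if (is.null(background_temp)) background_temp <- trace$temp_c[1]
    amplitude <- max(abs(trace$temp_c - background_temp))
  }
  units <- sample_population_units(spec, seed)
  intens <- channel_intensities(units, trace, background_temp,
                                decoder$window)
  ro_stim <- simulate_count_readouts(intens, n_trials,
                                     seed = child_seed(seed, "stim-trials"),
                                     null = FALSE, window = decoder$window)
  ro_null <- simulate_count_readouts(intens, n_trials,
                                     seed = child_seed(seed, "null-trials"),
                                     null = TRUE, window = decoder$window)
  null_sd <- c(
    a = stats::sd(ro_null$pool_a_count - ro_null$pool_a_baseline),
    b = stats::sd(ro_null$pool_b_baseline - ro_null$pool_b_count)
  )
  stat_stim <- decision_statistic(ro_stim, decoder, null_sd)
  stat_null <- decision_statistic(ro_null, decoder, null_sd)
  criterion <- if (is.null(decoder$criterion)) {
    as.numeric(stats::quantile(stat_null, 0.95, type = 1))
  } else decoder$criterion
  h <- mean(stat_stim > criterion)
  fa <- mean(stat_null > criterion)
  v <- (stats::var(stat_stim) + stats::var(stat_null)) / 2
  degenerate <- v <= 0
  structure(list(
    genotype = spec$genotype,
    baseline_c = background_temp,
    amplitude_c = amplitude,
    area_mm2 = spec$area,
    mode = decoder$mode,
    window_s = decoder$window,
    n_trials = n_trials,
    predicted_dprime = dprime(h, fa, n_trials, n_trials),
    dprime_gaussian = if (degenerate) 0 else
      (mean(stat_stim) - mean(stat_null)) / sqrt(v),
    degenerate = degenerate,
    hit_rate = h, fa_rate = fa, criterion = criterion,
    null_sd = null_sd,
    n_a = intens$n_a, n_b = intens$n_b,
    intensities = intens,
    stat_stim = stat_stim, stat_null = stat_null,
    labels = discriminate_warm_cool(ro_stim, decoder, null_sd)
  ), class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf(
    paste0("<model_result> %s, %+.3g degC from %.3g degC, %.3g mm2, ",
           "%s decoder\n  predicted d' = %.2f (gaussian %.2f), ",
           "h = %.2f, fa = %.2f, pools A/B = %d/%d\n"),
    x$genotype, x$amplitude_c, x$baseline_c, x$area_mm2, x$mode,
    x$predicted_dprime, x$dprime_gaussian, x$hit_rate, x$fa_rate,
    x$n_a, x$n_b))
  invisible(x)
}

#' In-silico lesion experiment over genotype presets
#'
#' Runs \code{\link{model_dprime}} for each genotype and stimulus
#' amplitude on a common population specification, the model analogue of
#' training knockout cohorts on the detection task.
#'
#' @param genotypes Character vector of preset names.
#' @param amplitudes Stimulus amplitudes, degC (step from
#'   \code{baseline_temp}).
#' @param baseline_temp Baseline temperature, degC.
#' @param decoder A \code{\link{decoder_params}}.
#' @param n_trials Trials per condition.
#' @param seed Integer seed.
#' @param spec Base \code{\link{population_spec}} to which each genotype
#'   preset is applied.
#' @return A data.frame with one row per genotype x amplitude:
#'   \code{genotype}, \code{amplitude_c}, \code{predicted_dprime},
#'   \code{dprime_gaussian}, \code{hit_rate}, \code{fa_rate},
#'   \code{n_a}, \code{n_b}.
#' @export
lesion_experiment <- function(genotypes, amplitudes, baseline_temp = 32,
                              decoder = decoder_params(), n_trials = 200,
                              seed = 1, spec = population_spec()) {
  rows <- list()
  for (g in genotypes) {
    gspec <- apply_genotype(spec, g)
    for (a in amplitudes) {
      stim <- step_waveform_params(baseline_temp = baseline_temp,
                                   target_temp = baseline_temp + a)
      res <- model_dprime(gspec, stim, decoder, n_trials,
                          seed = child_seed(seed, paste0(g, "-", a)))
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = g, amplitude_c = a,
        predicted_dprime = res$predicted_dprime,
        dprime_gaussian = res$dprime_gaussian,
        hit_rate = res$hit_rate, fa_rate = res$fa_rate,
        n_a = res$n_a, n_b = res$n_b, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Predicted sensitivity as a function of stimulated skin area
#'
#' Spatial summation: the model pools more fibers as the contact area
#' grows, so the predicted d-prime is non-decreasing in area in
#' expectation.
#'
#' @param spec Base \code{\link{population_spec}}.
#' @param areas Vector of contact areas, mm2.
#' @param stimulus A \code{\link{step_waveform_params}}.
#' @param decoder A \code{\link{decoder_params}}.
#' @param n_trials Trials per area.
#' @param seed Integer seed.
#' @return A data.frame with \code{area_mm2}, \code{predicted_dprime},
#'   \code{dprime_gaussian} and pool sizes.
#' @export
spatial_summation_curve <- function(spec, areas,
                                    stimulus = step_waveform_params(),
                                    decoder = decoder_params(),
                                    n_trials = 200, seed = 1) {
  if (any(areas <= 0)) stop("areas must be > 0", call. = FALSE)
  rows <- lapply(areas, function(a) {
    aspec <- spec
    aspec$area <- a
    res <- model_dprime(aspec, stimulus, decoder, n_trials,
                        seed = child_seed(seed, paste0("area-", a)))
    data.frame(area_mm2 = a, predicted_dprime = res$predicted_dprime,
               dprime_gaussian = res$dprime_gaussian, n_a = res$n_a,
               n_b = res$n_b)
  })
  do.call(rbind, rows)
}

#' How many fibers carry innocuous-temperature information?
#'
#' The innervation-density arithmetic: with a C-fiber density of
#' 176 fibers/mm2 and ~36 percent of C-fibers responsive to innocuous
#' temperature change, more than 60 fibers/mm2 carry warm-related
#' information, and a ~22 mm2 contact recruits more than 1300 such
#' fibers.
#'
#' @param density Fiber density, fibers/mm2.
#' @param thermo_fraction Fraction responsive to innocuous temperature
#'   change.
#' @param area Stimulated area, mm2.
#' @return A list with \code{per_mm2} and \code{total}.
#' @export
#' @examples
#' informative_fiber_budget(176, 0.36, 22)  # 63.36 / mm2, ~1394 total
informative_fiber_budget <- function(density = 176,
                                     thermo_fraction = 0.36, area = 22) {
  if (density <= 0 || area <= 0 || thermo_fraction < 0) {
    stop("inputs must be positive", call. = FALSE)
  }
  per <- density * thermo_fraction
  list(per_mm2 = per, total = per * area)
}

#' Build a unit-record table from explicit fiber parameter objects
#'
#' Convenience for constructing small, fully specified populations (e.g.
#' for closed-form checks) without sampling.
#'
#' @param fibers List of \code{\link{fiber_params}} objects.
#' @return A unit-record data.frame compatible with
#'   \code{\link{channel_intensities}} and
#'   \code{\link{simulate_population}}.
#' @export
units_from_fibers <- function(fibers) {
  stopifnot(length(fibers) >= 1,
            all(vapply(fibers, inherits, logical(1), "fiber_params")))
  rows <- lapply(seq_along(fibers), function(i) {
    f <- fibers[[i]]
    warm <- f$kind == "warm_excited"
    data.frame(
      unit_id = i, class_label = f$class_label, kind = f$kind, cv = f$cv,
      responds_mech = f$class_label != "C-C",
      responds_heat = warm,
      responds_cold = !warm,
      is_ongoing = !warm && f$ongoing_rate > 0,
      t_on = if (warm) f$t_on else NA_real_,
      gain = if (warm) f$gain else NA_real_,
      r_max = f$r_max,
      noxious_cutoff = if (warm) f$noxious_cutoff else Inf,
      noxious_scale = if (warm) f$noxious_scale else 1,
      ongoing_rate = if (warm) 0 else f$ongoing_rate,
      cool_gain = if (warm) 0 else f$cool_gain,
      warm_suppression_gain = if (warm) 0 else f$warm_suppression_gain,
      refractory = f$refractory,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
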