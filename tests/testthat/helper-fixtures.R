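# Shared small builders for the suite.

# A per-test temporary file cleaned up with the test environment.
withr_local_file <- function(name, env = parent.frame()) {
  path <- file.path(tempdir(), paste0(sample.int(1e9, 1), "-", name))
  cleanup <- bquote(unlink(c(.(path), .(paste0(path, ".meta.json")))))
  do.call(on.exit, list(cleanup, add = TRUE), envir = env)
  path
}

# A deterministic session log: explicit trials and licks, no simulation.
manual_log <- function(onsets_stim, onsets_catch, licks,
                       rewards = numeric(0), amplitude = 10,
                       lockout = 2, window = 3.5) {
  onsets <- sort(c(onsets_stim, onsets_catch))
  type <- ifelse(onsets %in% onsets_stim, "stimulus", "catch")
  session_log(
    data.frame(trial_id = seq_along(onsets), type = type,
               onset_s = onsets,
               amplitude_c = ifelse(type == "stimulus", amplitude, 0)),
    licks = licks, rewards = rewards,
    meta = list(pre_stim_lockout = lockout, response_window = window)
  )
}

# A constant-temperature trace of the given span.
constant_trace <- function(temp, span, rate = 10) {
  t <- seq(0, span, by = 1 / rate)
  temperature_trace(t, rep(temp, length(t)))
}

# Baseline-then-step trace: `pre` seconds at baseline, then a step
# waveform; stimulus onset is at t = pre.
baseline_then_step <- function(params, pre, rate = 100) {
  step <- make_step_waveform(params, rate)
  pre_t <- seq(0, pre - 1 / rate, by = 1 / rate)
  temperature_trace(c(pre_t, pre + step$time_s),
                    c(rep(params$baseline_temp, length(pre_t)),
                      step$temp_c))
}
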