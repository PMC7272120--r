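#!/usr/bin/env Rscript
# Simulate the behavioural data set: a 10-session warm-detection training
# course for a synthetic wild-type observer (learning modelled as a lapse
# rate that falls across sessions), plus a descending-amplitude threshold
# series (6, 4, 2, 1, 0.5 degC) for the trained observer. Writes raw
# session event logs under results/behavior/.

library(thermocode)

SEED <- 1
out_dir <- "results/behavior"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

# Training course: detection improves as the observer learns the
# stimulus-reward contingency; asymptotic performance from session ~5 on.
lapse_by_session <- pmax(0.9 - 0.2 * (1:10), 0.08)
for (i in 1:10) {
  obs <- observer_params(lapse = lapse_by_session[i])
  log <- simulate_session(
    session_schedule(seed = child_seed(SEED, paste0("train-", i))), obs)
  write_session_log(file.path(out_dir, sprintf("training_day%02d.csv", i)),
                    log)
}
cat("wrote 10 training sessions to", out_dir, "\n")

# Threshold series with the fully trained observer.
amps <- c(6, 4, 2, 1, 0.5)
for (a in amps) {
  log <- simulate_session(
    session_schedule(stimulus = step_waveform_params(32, 32 + a),
                     seed = child_seed(SEED, paste0("thresh-", a))),
    observer_params())
  write_session_log(file.path(out_dir, sprintf("threshold_%gC.csv", a)),
                    log)
}
cat("wrote", length(amps), "threshold sessions (amplitudes",
    paste(amps, collapse = ", "), "degC)\n")
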