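#!/usr/bin/env Rscript
# Simulate and analyse the afferent recordings: a population of forepaw
# fibers under the behavioural 32->42 degC step and the 1 degC/s search
# ramp at a 27 degC physiological skin temperature. Classifies units,
# measures thermal thresholds, ongoing activity, warm-evoked suppression,
# and spike PSTHs of the warm-excited and warm-inhibited channels.
# Writes tables under results/afferents/.

library(thermocode)

SEED <- 1
out_dir <- "results/afferents"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

# A small recorded sample (a few hundred fibers, like a recording
# campaign, not the whole paw) keeps spike simulation cheap.
spec <- population_spec(density = 20, area = 22)
bg <- 27

# 60 s stimulus-free baseline to characterise ongoing activity, then the
# behavioural warm step.
step <- step_waveform_params(32, 42)
pre <- 60
step_tr <- make_step_waveform(step, 200)
pre_t <- seq(0, pre - 0.005, by = 0.005)
trace <- temperature_trace(c(pre_t, pre + step_tr$time_s),
                           c(rep(bg, length(pre_t)), step_tr$temp_c))
pop <- simulate_population(spec, trace, bg, seed = SEED)
units <- pop$units

# unit classification from conduction velocity and modality flags
# (thermosensitive units only; mechano-only units fall outside the
# thermosensory labelling scheme)
units$class_check <- classify_fiber(units$cv, units$responds_mech,
                                    units$responds_heat,
                                    units$responds_cold)
thermo <- units$kind != "silent"
stopifnot(all(units$class_check[thermo] == units$class_label[thermo]))

# ongoing activity in the baseline epoch
oa <- lapply(pop$trains, ongoing_activity, baseline_window = c(0, pre))
units$ongoing_rate_hz <- vapply(oa, `[[`, numeric(1), "rate")
units$is_ongoing_obs <- vapply(oa, `[[`, logical(1), "is_ongoing")
tonic <- units$is_ongoing_obs
cat(sprintf("%d of %d thermosensitive units show ongoing activity (%.0f%%),",
            sum(tonic), sum(units$kind != "silent"),
            100 * mean(tonic[units$kind != "silent"])),
    sprintf("rates %.1f-%.1f Hz\n",
            min(units$ongoing_rate_hz[tonic]),
            max(units$ongoing_rate_hz[tonic])))

# warm-evoked suppression of the tonic units during the step plateau
units$rate_change_pct <- vapply(seq_len(nrow(units)), function(i) {
  rate_change_index(pop$trains[[i]], c(0, pre), c(pre + 0.5, pre + 3.5))
}, numeric(1))
cat(sprintf("median rate change of tonic units under the warm step: %.0f%%\n",
            median(units$rate_change_pct[tonic], na.rm = TRUE)))

# thermal thresholds of warm-excited units on the 1 degC/s search ramp
ramp <- make_linear_ramp(ramp_params(32, 48, 1), 200)
ramp_pop <- simulate_population(spec, ramp, bg,
                                seed = child_seed(SEED, "ramp"))
units$warm_threshold_c <- vapply(seq_len(nrow(units)), function(i)
  thermal_threshold(ramp_pop$trains[[i]], ramp), numeric(1))
warm_idx <- units$kind == "warm_excited" & !is.na(units$warm_threshold_c)
units$nonnoxious <- NA
units$nonnoxious[warm_idx] <- vapply(
  units$warm_threshold_c[warm_idx],
  function(w) is_nonnoxious_responsive(warm_threshold = w), logical(1))
cat(sprintf("%.0f%% of threshold-bearing warm-excited units respond below 42 degC\n",
            100 * mean(units$nonnoxious[warm_idx])))

write_units(file.path(out_dir, "units.json"), units)
write.csv(as.data.frame(table(class = units$class_label)),
          file.path(out_dir, "class_counts.csv"), row.names = FALSE)

# population PSTHs: warm-excited vs warm-inhibited channels, 32->42 step
we <- which(units$kind == "warm_excited")
tn <- which(tonic)
psth_we <- spike_psth(pop$trains[we], onsets = pre, bin_width = 0.25,
                      window = c(-2, 4))
psth_tn <- spike_psth(pop$trains[tn], onsets = pre, bin_width = 0.25,
                      window = c(-2, 4))
psth <- data.frame(psth_we[1:2], warm_excited_hz = psth_we$rate_hz,
                   warm_inhibited_hz = psth_tn$rate_hz)
write.csv(psth, file.path(out_dir, "psth_step_32_42.csv"),
          row.names = FALSE)
cat(sprintf(paste0("PSTH during the step: warm-excited channel %.2f -> ",
                   "%.2f Hz, warm-inhibited channel %.2f -> %.2f Hz ",
                   "(baseline -> plateau)\n"),
            mean(psth$warm_excited_hz[psth$bin_start_s < 0]),
            mean(psth$warm_excited_hz[psth$bin_start_s >= 0.5 &
                                        psth$bin_end_s <= 3.5]),
            mean(psth$warm_inhibited_hz[psth$bin_start_s < 0]),
            mean(psth$warm_inhibited_hz[psth$bin_start_s >= 0.5 &
                                          psth$bin_end_s <= 3.5])))
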