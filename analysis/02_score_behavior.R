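#!/usr/bin/env Rscript
# Score the simulated behaviour: per-session hit/false-alarm rates and
# corrected d-prime across training, the first-lick PSTH of the trained
# observer, mean lick latency, and the perceptual threshold from the
# descending amplitude series. Reads results/behavior/, writes summary
# tables under results/.

library(thermocode)

in_dir <- "results/behavior"
dir.create("results", showWarnings = FALSE)

train_files <- sort(list.files(in_dir, "^training_day[0-9]+\\.csv$",
                               full.names = TRUE))
stopifnot(length(train_files) == 10)
logs <- lapply(train_files, read_session_log)

lc <- learning_curve(logs)
lc$learned <- lc$hf_diff_lo > 0
write.csv(lc, "results/learning_curve.csv", row.names = FALSE)
first_learned <- which(lc$learned)[1]
cat(sprintf("learning curve: d' rises from %.2f to %.2f; hit > false-alarm",
            lc$dprime[1], lc$dprime[10]),
    sprintf("(95%% bootstrap CI) from session %d on\n", first_learned))

day10 <- logs[[10]]
psth <- lick_psth(day10, bin_width = 0.25, window = c(0, 4),
                  normalization = "probability")
write.csv(psth, "results/lick_psth_day10.csv", row.names = FALSE)
lat <- first_lick_latencies(day10)
cat(sprintf("day 10: mean first-lick latency %.2f s over %d hits\n",
            mean(lat), length(lat)))

amps <- c(6, 4, 2, 1, 0.5)
th_logs <- lapply(amps, function(a)
  read_session_log(file.path(in_dir, sprintf("threshold_%gC.csv", a))))
series <- threshold_series(th_logs, amps)
write.csv(series, "results/threshold_series.csv", row.names = FALSE)
th <- estimate_threshold(series)
cat(sprintf("perceptual threshold (d' >= 1 and CI excludes 0): %g degC\n",
            th))
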