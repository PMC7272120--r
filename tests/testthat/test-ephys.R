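test_that("conduction velocity is distance over latency", {
  expect_equal(conduction_velocity(0.01, 0.02), 0.5)
  expect_equal(conduction_velocity(0.01, 0.002), 5)
  expect_error(conduction_velocity(0.01, 0), "latency")
  expect_error(conduction_velocity(-0.01, 0.01), "> 0")
})

test_that("fiber classification follows velocity and modality rules", {
  expect_equal(classify_fiber(0.5, TRUE, TRUE, FALSE), "C-MH")
  expect_equal(classify_fiber(0.5, TRUE, TRUE, TRUE), "C-MHC")
  expect_equal(classify_fiber(0.5, TRUE, FALSE, TRUE), "C-MC")
  expect_equal(classify_fiber(0.5, FALSE, FALSE, TRUE), "C-C")
  expect_equal(classify_fiber(5, TRUE, TRUE, FALSE), "A-MH")
  expect_equal(classify_fiber(5, TRUE, FALSE, TRUE), "A-MC")
  # boundary velocities: 1.2 and 10 m/s are A-delta, above 10 is A-beta
  expect_equal(classify_fiber(1.2, TRUE, TRUE, FALSE), "A-MH")
  expect_equal(classify_fiber(10, TRUE, TRUE, FALSE), "A-MH")
  expect_equal(classify_fiber(15, TRUE, TRUE, FALSE), "A-beta")
  # totality: heat-only, mech-only, unresponsive
  expect_equal(classify_fiber(0.5, FALSE, TRUE, FALSE), "C-H")
  expect_equal(classify_fiber(0.5, TRUE, FALSE, FALSE), "C-M")
  expect_equal(classify_fiber(0.5, FALSE, FALSE, FALSE),
               "non-thermosensory")
  expect_error(classify_fiber(0, TRUE, TRUE, FALSE), "velocity")
})

test_that("classification of a sampled population recovers the class mix", {
  spec <- population_spec(density = 500, area = 10, thermo_fraction = 1,
                          ongoing_fraction = 0)
  u <- sample_population_units(spec, seed = 6)
  lab <- classify_fiber(u$cv, u$responds_mech, u$responds_heat,
                        u$responds_cold)
  expect_equal(lab, u$class_label)   # flags and cv are self-consistent
})

test_that("thermal threshold reads the trace at the first spike", {
  ramp <- make_linear_ramp(ramp_params(32, 48, 1), 100)
  tr <- spike_train(c(5, 6.5, 8), span = 16)
  expect_equal(thermal_threshold(tr, ramp), 37)
  expect_true(is.na(thermal_threshold(spike_train(numeric(0), span = 16),
                                      ramp)))
  # first spike during the hold phase of a step reads the plateau
  step <- make_step_waveform(step_waveform_params(32, 42), 100)
  expect_equal(thermal_threshold(spike_train(2, span = 4), step), 42)
  # misaligned spans are an error
  expect_error(thermal_threshold(spike_train(20, span = 20), ramp),
               "span")
})

test_that("non-noxious responsiveness uses the 42/22 degC bounds", {
  expect_true(is_nonnoxious_responsive(warm_threshold = 40))
  expect_false(is_nonnoxious_responsive(warm_threshold = 45))
  expect_true(is_nonnoxious_responsive(cold_threshold = 25))
  expect_false(is_nonnoxious_responsive(cold_threshold = 20))
  expect_true(is_nonnoxious_responsive(warm_threshold = 45,
                                       cold_threshold = 25))
  expect_error(is_nonnoxious_responsive(), "threshold")
})

test_that("ongoing activity requires the floor rate in both window halves", {
  tr <- spike_train(seq(0.25, 30, 0.5), span = 60)   # 2 Hz, regular
  oa <- ongoing_activity(tr, c(0, 30))
  expect_equal(oa$rate, 2)
  expect_true(oa$is_ongoing)

  expect_false(ongoing_activity(spike_train(numeric(0), span = 30),
                                c(0, 30))$rate > 0)
  # bursty train: all spikes in the first half fails persistence
  burst <- spike_train(seq(0.1, 10, 0.1), span = 60)
  expect_false(ongoing_activity(burst, c(0, 60))$is_ongoing)
  expect_warning(ongoing_activity(tr, c(0, 5)), "shorter than 10 s")
})

test_that("simulated tonic fibers are all flagged as ongoing over 60 s", {
  tr <- constant_trace(27, 60)
  set.seed(2)
  rates <- runif(20, 0.2, 6)
  flagged <- vapply(seq_along(rates), function(i) {
    f <- tonic_fiber(rates[i])
    ongoing_activity(simulate_fiber(f, tr, 27, seed = 1000 + i),
                     c(0, 60))$is_ongoing
  }, logical(1))
  expect_true(all(flagged))
})

test_that("rate change index measures percentage suppression", {
  # 2 Hz baseline (0-30 s), 0.5 Hz during stimulus (30-60 s)
  st <- spike_train(c(seq(0.25, 30, 0.5), seq(31, 59, 2)), span = 60)
  expect_equal(rate_change_index(st, c(0, 30), c(30, 60)), -75)
  # complete silencing
  sil <- spike_train(seq(0.25, 30, 0.5), span = 60)
  expect_equal(rate_change_index(sil, c(0, 30), c(30, 60)), -100)
  # no change
  flat <- spike_train(seq(0.25, 60, 0.5), span = 60)
  expect_equal(rate_change_index(flat, c(0, 30), c(30, 60)), 0)
  # zero baseline is undefined
  expect_true(is.na(rate_change_index(spike_train(c(31, 32), span = 60),
                                      c(0, 30), c(30, 60))))
  expect_error(rate_change_index(flat, c(0, 30), c(20, 60)), "overlap")
})

test_that("default tonic suppression silences under a 10 degC warm step", {
  # generator contract: rate change <= -90 percent with default gain
  tr <- baseline_then_step(step_waveform_params(32, 42, 0.5, 30, 0.5),
                           pre = 31)
  rci <- vapply(1:10, function(s) {
    f <- tonic_fiber(ongoing_rate = 3)   # default suppression 0.2 per degC
    st <- simulate_fiber(f, tr, 32, seed = 200 + s)
    rate_change_index(st, c(0, 31), c(31.5, 61.5))
  }, numeric(1))
  expect_lt(mean(rci), -90)
})

test_that("spike PSTH computes mean rates with exact conservation", {
  tr <- spike_train(c(1.1, 1.2, 1.3, 1.4), span = 10)
  ps <- spike_psth(tr, onsets = 1, bin_width = 0.5, window = c(0, 2))
  expect_equal(ps$rate_hz[ps$bin_start_s == 0], 8)  # 4 spikes / 0.5 s
  expect_equal(sum(ps$count), 4)

  # conservation on random inputs
  set.seed(44)
  trains <- lapply(1:5, function(i)
    spike_train(sort(sample(seq(0.001, 50, 0.001), 200)), span = 50))
  onsets <- c(5, 15, 25, 35)
  ps2 <- spike_psth(trains, onsets, bin_width = 0.3, window = c(-1, 4))
  manual <- sum(vapply(trains, function(tr) {
    sum(vapply(onsets, function(on) {
      sum(tr$spike_times - on > -1 & tr$spike_times - on <= 4)
    }, numeric(1)))
  }, numeric(1)))
  expect_equal(sum(ps2$count), manual)
  expect_equal(sum(ps2$rate_hz * diff(c(ps2$bin_start_s, 4))) *
                 length(onsets) * length(trains), manual,
               tolerance = 1e-9)
})

test_that("a homogeneous 5 Hz process gives flat PSTH bins", {
  f <- tonic_fiber(ongoing_rate = 5, refractory = 0)
  tr <- constant_trace(27, 5)
  trains <- lapply(1:200, function(s) simulate_fiber(f, tr, 27, seed = s))
  ps <- spike_psth(trains, onsets = 0, bin_width = 0.5, window = c(0, 5))
  # each bin pools 200 x 0.5 s: SE = sqrt(5 / (200 * 0.5)) = 0.22 Hz
  expect_true(all(abs(ps$rate_hz - 5) < 3 * sqrt(5 / 100)))
})

test_that("monotonicity classification separates preferring tuning", {
  temps <- seq(32, 48, 4)
  expect_equal(as.character(monotonicity_class(temps, c(0, 2, 5, 9, 14))),
               "monotonic")
  expect_equal(as.character(monotonicity_class(temps, c(0, 6, 9, 4, 1))),
               "preferring")
  flat <- monotonicity_class(temps, rep(0, 5))
  expect_equal(as.character(flat), "monotonic")
  expect_false(attr(flat, "responsive"))
  # peak at the end is monotonic even if non-monotone en route
  expect_equal(as.character(monotonicity_class(temps, c(0, 3, 2, 5, 9))),
               "monotonic")
  expect_error(monotonicity_class(c(32, 40), c(0, 1)), "grid")
})

test_that("warm threshold recovery tracks the generating t_on", {
  # mean first-spike temperature exceeds t_on by the first-arrival delay
  f <- warm_fiber(t_on = 38, gain = 2, r_max = 50)
  ramp <- make_linear_ramp(ramp_params(32, 48, 1), 200)
  th <- vapply(1:50, function(s) {
    thermal_threshold(simulate_fiber(f, ramp, 32, seed = 300 + s), ramp)
  }, numeric(1))
  expect_true(all(!is.na(th)))
  expect_true(all(th >= 38))
  expect_lt(mean(th) - 38, 1)
})

test_that("unit record JSON round trips", {
  u <- sample_population_units(population_spec(density = 10, area = 2),
                               seed = 1)
  path <- withr_local_file("units.json")
  write_units(path, u)
  back <- read_units(path)
  expect_equal(back$class_label, u$class_label)
  expect_equal(back$cv, u$cv, tolerance = 1e-12)
  expect_equal(back$ongoing_rate, u$ongoing_rate, tolerance = 1e-12)
})

test_that("spike CSV round trips preserve trains", {
  trains <- list(spike_train(c(0.5, 1.25, 2), unit_id = 1, span = 10),
                 spike_train(c(3.3333333), unit_id = 2, span = 10))
  path <- withr_local_file("spikes.csv")
  write_spikes(path, trains)
  back <- read_spikes(path, span = 10)
  expect_equal(back[["1"]]$spike_times, trains[[1]]$spike_times,
               tolerance = 1e-6)
  expect_equal(back[["2"]]$spike_times, trains[[2]]$spike_times,
               tolerance = 1e-6)
})
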