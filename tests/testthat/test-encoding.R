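test_that("informative fiber budget arithmetic", {
  b <- informative_fiber_budget(176, 0.36, 22)
  expect_equal(b$per_mm2, 63.36)
  expect_equal(b$total, 1393.92)
  expect_equal(informative_fiber_budget(176, 0, 22)$total, 0)
  expect_error(informative_fiber_budget(0, 0.36, 22), "positive")
})

test_that("channel intensities are additive: doubling fibers doubles counts", {
  fibers <- list(warm_fiber(t_on = 35, gain = 2),
                 tonic_fiber(3, warm_suppression_gain = 0.2))
  u1 <- units_from_fibers(fibers)
  u2 <- units_from_fibers(c(fibers, fibers))
  tr <- make_step_waveform(step_waveform_params(), 200)
  i1 <- channel_intensities(u1, tr, 32, window = 1)
  i2 <- channel_intensities(u2, tr, 32, window = 1)
  expect_equal(i2$a_stim, 2 * i1$a_stim)
  expect_equal(i2$b_stim, 2 * i1$b_stim)
  expect_equal(i2$b_base, 2 * i1$b_base)
  expect_equal(i1$b_base, 3)   # 3 Hz x 1 s baseline window
})

test_that("decision statistic implements the sum and coincidence rules", {
  ro <- channel_readout(pool_a_count = 12, pool_a_baseline = 2,
                        pool_b_count = 5, pool_b_baseline = 9)
  expect_equal(decision_statistic(ro, decoder_params("sum")), 14)
  # sum equals excitation evidence when suppression evidence is zero
  ro_e <- channel_readout(12, 2, 7, 7)
  expect_equal(decision_statistic(ro_e, decoder_params("sum")), 10)
  # coincidence: large excitation with zero suppression carries no evidence
  stat <- decision_statistic(ro_e, decoder_params("coincidence"),
                             null_sd = c(a = 2, b = 2))
  expect_lte(stat, 0)
  # min rule with explicit normalisation
  stat2 <- decision_statistic(ro, decoder_params("coincidence"),
                              null_sd = c(a = 2, b = 2))
  expect_equal(stat2, min(10 / 2, 4 / 2))
  expect_error(channel_readout(-1, 0, 0, 0), "counts")
})

test_that("population readout pools counts per channel from spike trains", {
  # explicit trains around an onset at t = 10, window 1 s
  units <- units_from_fibers(list(warm_fiber(35), warm_fiber(36),
                                  tonic_fiber(3), tonic_fiber(2)))
  trains <- list(
    spike_train(c(10.1, 10.5), span = 20),         # pool A, 2 in window
    spike_train(c(9.5, 10.9), span = 20),          # pool A, 1 + 1 baseline
    spike_train(c(9.2, 9.8, 10.4), span = 20),     # pool B
    spike_train(c(9.1, 9.9), span = 20)            # pool B
  )
  ro <- population_readout(trains, units, onset = 10, window = 1)
  expect_equal(ro$pool_a_count, 3)
  expect_equal(ro$pool_a_baseline, 1)
  expect_equal(ro$pool_b_count, 1)
  expect_equal(ro$pool_b_baseline, 4)
  expect_equal(ro$n_a, 2)
  expect_equal(ro$n_b, 2)

  zero <- lapply(1:4, function(i) spike_train(numeric(0), span = 20))
  ro0 <- population_readout(zero, units, onset = 10, window = 1)
  expect_equal(ro0$pool_a_count + ro0$pool_b_count +
                 ro0$pool_a_baseline + ro0$pool_b_baseline, 0)
  expect_warning(population_readout(list(), units[0, ], 10), "no units")
})

test_that("tonic pool counts drop under a warm step, on average", {
  units <- units_from_fibers(lapply(1:20, function(i) tonic_fiber(3)))
  tr <- baseline_then_step(step_waveform_params(), pre = 2)
  drops <- vapply(1:15, function(s) {
    trains <- lapply(seq_len(nrow(units)), function(i)
      simulate_fiber(unit_fiber(units[i, ]), tr, 32,
                     seed = 7000 + 97 * s + i, unit_id = i))
    ro <- population_readout(trains, units, onset = 2, window = 1)
    ro$pool_b_baseline - ro$pool_b_count
  }, numeric(1))
  expect_gt(mean(drops), 0)
  expect_gt(t.test(drops)$statistic, 3)
})

test_that("ongoing-activity identification can drive pool membership", {
  units <- units_from_fibers(list(warm_fiber(35), tonic_fiber(3)))
  units$is_ongoing <- NULL
  trains <- list(spike_train(c(30.2, 30.4), span = 40),
                 spike_train(seq(0.5, 40, 0.5), span = 40))
  ro <- population_readout(trains, units, onset = 30, window = 1,
                           ongoing_epoch = c(0, 29))
  expect_equal(ro$n_b, 1)
  expect_equal(ro$pool_a_count, 2)
  expect_error(population_readout(trains, units, onset = 30), "ongoing")
})

test_that("warm/cool/none discrimination follows the two-channel rule", {
  dec <- decoder_params(z_crit = 1.64)
  nsd <- c(a = 2, b = 2)
  warm <- channel_readout(10, 1, 2, 10)   # e = 9, s = 8: both channels
  expect_equal(discriminate_warm_cool(warm, dec, nsd), "warm")
  cool <- channel_readout(1, 1, 18, 8)    # pool B excited, pool A silent
  expect_equal(discriminate_warm_cool(cool, dec, nsd), "cool")
  none <- channel_readout(2, 1, 8, 8)
  expect_equal(discriminate_warm_cool(none, dec, nsd), "none")
  # excitation without suppression is not warm
  e_only <- channel_readout(10, 1, 8, 8)
  expect_equal(discriminate_warm_cool(e_only, dec, nsd), "none")
})

test_that("model d-prime is reproducible and reports sane fields", {
  spec <- population_spec(seed = 1)
  r1 <- model_dprime(spec, step_waveform_params(), n_trials = 100,
                     seed = 5)
  r2 <- model_dprime(spec, step_waveform_params(), n_trials = 100,
                     seed = 5)
  expect_equal(r1$predicted_dprime, r2$predicted_dprime)
  expect_equal(r1$stat_stim, r2$stat_stim)
  expect_true(is.finite(r1$predicted_dprime))
  expect_equal(r1$amplitude_c, 10)
  expect_equal(r1$n_trials, 100)
  expect_error(model_dprime(spec, step_waveform_params(), n_trials = 50),
               "n_trials")
})

test_that("null stimulus gives chance-level model d-prime in both modes", {
  spec <- population_spec(seed = 2)
  null_stim <- step_waveform_params(32, 32)
  for (mode in c("sum", "coincidence")) {
    res <- model_dprime(spec, null_stim, decoder_params(mode),
                        n_trials = 400, seed = 11)
    expect_lt(abs(res$dprime_gaussian), 3 * sqrt(2 / 400))
    expect_lt(abs(res$predicted_dprime), 0.6)
  }
})

test_that("degenerate zero-variance statistics are flagged", {
  # a population with no fibers in either pool
  spec <- population_spec(density = 10, area = 10, thermo_fraction = 0,
                          seed = 1)
  res <- model_dprime(spec, step_waveform_params(), n_trials = 100,
                      seed = 1)
  expect_true(res$degenerate)
  expect_equal(res$dprime_gaussian, 0)
  expect_equal(res$predicted_dprime, 0)
})

test_that("lesion grids cover genotype x amplitude and validate names", {
  grid <- lesion_experiment(c("wildtype", "trpm8_null"), c(2, 10),
                            n_trials = 100, seed = 3,
                            spec = population_spec())
  expect_equal(nrow(grid), 4)
  expect_true(all(grid$n_b[grid$genotype == "trpm8_null"] == 0))
  expect_error(lesion_experiment("unknown_gene", 10, n_trials = 100),
               "unknown genotype")
})

test_that("wildtype and tko both detect a 22->32 degC step via suppression", {
  stim <- step_waveform_params(22, 32)
  for (g in c("wildtype", "tko")) {
    spec <- population_spec(genotype = g, seed = 4)
    res <- model_dprime(spec, stim, decoder_params("sum"),
                        n_trials = 200, seed = 13)
    expect_gt(res$predicted_dprime, 1)
    # the excitation channel contributes almost nothing at a 22 C baseline
    expect_lt(res$intensities$a_stim, 0.05 * res$intensities$b_base)
  }
})

test_that("spatial summation: area grows the pooled fiber count and d-prime", {
  curve <- spatial_summation_curve(population_spec(), areas = c(4, 22, 60),
                                   stimulus = step_waveform_params(32, 33),
                                   decoder = decoder_params("sum"),
                                   n_trials = 200, seed = 9)
  expect_true(all(diff(curve$n_a + curve$n_b) > 0))
  expect_gt(cor(curve$area_mm2, curve$dprime_gaussian,
                method = "spearman"), 0.9)
  expect_error(spatial_summation_curve(population_spec(), areas = c(0, 5)),
               "areas")
})
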