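test_that("trial scoring applies the half-open response window", {
  log <- manual_log(onsets_stim = 10, onsets_catch = 20,
                    licks = c(11, 25))
  sc <- score_trials(log, window = 3.5)
  expect_equal(sc$outcome, c("hit", "correct_rejection"))
  expect_equal(sc$first_lick_latency_s[1], 1)

  # first lick 4.0 s after onset is outside the 3.5 s window
  miss <- score_trials(manual_log(10, 20, licks = 14.0), 3.5)
  expect_equal(miss$outcome[1], "miss")
  # a lick exactly at onset does not count; at onset + window it does
  expect_equal(score_trials(manual_log(10, 20, licks = 10), 3.5)$outcome[1],
               "miss")
  expect_equal(score_trials(manual_log(10, 20, licks = 13.5),
                            3.5)$outcome[1], "hit")
  # catch trials use an equally long window
  fa <- score_trials(manual_log(10, 20, licks = 23.4), 3.5)
  expect_equal(fa$outcome[2], "false_alarm")
})

test_that("scoring is invariant to licks outside all windows", {
  base <- manual_log(c(10, 40), c(25, 55), licks = c(11, 26.5))
  extra <- manual_log(c(10, 40), c(25, 55),
                      licks = c(2, 11, 18, 26.5, 35, 50, 70))
  expect_equal(score_trials(base)$outcome, score_trials(extra)$outcome)
})

test_that("lockout licks are flagged but do not change outcomes", {
  log <- manual_log(10, 20, licks = c(9.5, 11))
  sc <- score_trials(log)
  expect_equal(sc$n_lockout_licks[1], 1L)
  expect_equal(sc$outcome[1], "hit")
  expect_error(score_trials(log, window = 0), "window")
})

test_that("extreme rates receive the 1/(2N) boundary correction", {
  expect_equal(corrected_rate(1, 50), 0.99)
  expect_equal(corrected_rate(0, 50), 0.01)
  expect_equal(corrected_rate(0.6, 50), 0.6)
  expect_equal(corrected_rate(1, 20), 1 - 1 / 40)
  expect_error(corrected_rate(0.5, 0), "n must be")
  expect_error(corrected_rate(1.2, 50), "rate")
})

test_that("d-prime matches frozen oracle values and stays finite", {
  expect_equal(dprime(0.5, 0.5, 50, 50), 0)
  # frozen from the independent inverse-normal oracle
  expect_equal(dprime(0.9, 0.1, 50, 50), 2.5631031, tolerance = 1e-6)
  expect_equal(dprime(1, 0, 50, 50), 4.6526957, tolerance = 1e-6)
  expect_true(is.finite(dprime(1, 0, 1, 1)))
  expect_true(all(is.finite(
    outer(c(0, 0.3, 1), c(0, 0.7, 1),
          function(h, fa) dprime(h, fa, 50, 50)))))
})

test_that("d-prime is antisymmetric and monotone in its rates", {
  set.seed(31)
  for (i in 1:50) {
    h <- runif(1); fa <- runif(1); n <- sample(5:200, 1)
    expect_equal(dprime(h, fa, n, n), -dprime(fa, h, n, n))
  }
  h_grid <- seq(0.05, 0.95, 0.05)
  expect_true(all(diff(dprime(h_grid, 0.2, 50, 50)) > 0))
  expect_true(all(diff(dprime(0.8, h_grid, 50, 50)) < 0))
})

test_that("d-prime agrees with an independently coded inverse normal", {
  set.seed(17)
  for (i in 1:200) {
    h <- sample(0:20, 1) / 20
    fa <- sample(0:20, 1) / 20
    ns <- sample(2:400, 1)
    nc <- sample(2:400, 1)
    expect_equal(dprime(h, fa, ns, nc), dprime_oracle(h, fa, ns, nc),
                 tolerance = 1e-9)
  }
})

test_that("first-lick latencies come from hit trials only", {
  log <- manual_log(c(10, 40), 25, licks = c(11.2, 11.5, 26.2))
  expect_equal(first_lick_latencies(log), 1.2)   # miss trial emits nothing
})

test_that("lick PSTH bins first licks and conserves events", {
  log <- manual_log(10, 30, licks = 10.25)
  ps <- lick_psth(log, bin_width = 0.5, window = c(0, 4))
  expect_equal(sum(ps$stimulus), 1)
  expect_equal(ps$stimulus[ps$bin_start_s == 0], 1)
  expect_equal(sum(ps$catch), 0)

  # conservation across many trials with scattered licks
  set.seed(5)
  onsets <- seq(10, 400, by = 20)
  licks <- sort(c(onsets[c(TRUE, FALSE)] + runif(10, 0.1, 3.9),
                  runif(30, 0, 420)))
  log2 <- manual_log(onsets, onsets + 10, licks = licks)
  ps2 <- lick_psth(log2, bin_width = 0.25, window = c(0, 4))
  sc <- score_trials(log2, window = 4)
  expect_equal(sum(ps2$stimulus) + sum(ps2$catch),
               sum(!is.na(sc$first_lick_latency_s)))
})

test_that("a fixed-latency observer concentrates the PSTH in one bin", {
  onsets <- seq(10, 200, by = 20)
  log <- manual_log(onsets, onsets + 10, licks = onsets + 1.0)
  ps <- lick_psth(log, bin_width = 0.5, window = c(0, 4))
  nz <- ps[ps$stimulus > 0, ]
  expect_equal(nrow(nz), 1)
  expect_true(nz$bin_start_s < 1.0 & 1.0 <= nz$bin_end_s)
  expect_equal(nz$stimulus, length(onsets))
})

test_that("learning curve tracks per-session metrics and d-prime trends", {
  sched <- function(i) session_schedule(seed = 100 + i)
  # observer improving across sessions: rising asymptote via falling lapse
  logs <- lapply(1:5, function(i)
    simulate_session(sched(i),
                     observer_params(lapse = max(0.9 - 0.2 * i, 0)),
                     seed = 100 + i))
  lc <- learning_curve(logs, n_boot = 500)
  expect_equal(nrow(lc), 5)
  expect_gt(cor(lc$session, lc$dprime, method = "spearman"), 0.8)

  # single-session passthrough equals session_metrics
  m <- session_metrics(logs[[3]], n_boot = 0)
  expect_equal(lc$dprime[3], m$dprime)
  expect_equal(lc$hit_rate[3], m$hit_rate)
})

test_that("identical hit and false-alarm rates give d-prime 0", {
  onsets <- seq(10, 100, 10)
  log <- manual_log(onsets[1:5], onsets[6:10],
                    licks = onsets + 1)          # lick on every trial
  expect_equal(session_metrics(log, n_boot = 0)$dprime, 0)
})

test_that("threshold estimation applies the criterion-and-CI rule", {
  series <- data.frame(amplitude_c = c(6, 1, 0.5),
                       dprime = c(3.0, 1.6, 0.2),
                       hf_diff_lo = c(0.4, 0.2, -0.1))
  expect_equal(estimate_threshold(series), 1)
  none <- data.frame(amplitude_c = c(6, 1), dprime = c(0.5, 0.2),
                     hf_diff_lo = c(-0.1, -0.2))
  expect_true(is.na(estimate_threshold(none)))
  # d-prime alone is not enough: the CI must exclude zero
  shaky <- data.frame(amplitude_c = c(6, 1), dprime = c(3, 1.4),
                      hf_diff_lo = c(0.3, -0.05))
  expect_equal(estimate_threshold(shaky), 6)
  expect_error(estimate_threshold(series[1, ]), "amplitudes")
})

test_that("bootstrap CI separates clearly different rates", {
  set.seed(13)
  ci <- bootstrap_rate_difference(0.9, 0.1, 50, 50, n_boot = 5000)
  expect_gt(ci[1], 0)
  ci0 <- bootstrap_rate_difference(0.5, 0.5, 50, 50, n_boot = 5000)
  expect_lt(ci0[1], 0)
  expect_gt(ci0[2], 0)
})
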