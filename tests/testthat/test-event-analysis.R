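impulse_trace <- function(n = 4000, fs = 20, at = c(100), height = 5) {
  z <- numeric(n)
  t <- (seq_len(n) - 1) / fs
  for (a in at) z[round(a * fs) + 1] <- height
  dff_trace(t, dff = z, zdff = z, session_mean = 0, session_sd = 1, fs = fs)
}

test_that("align_to_events: identity, duplicates, boundary drops", {
  tr <- impulse_trace(at = 100)
  ev <- data.frame(event_type = "lever_extension", time_s = 100,
                   trial_index = 1L)
  m <- align_to_events(tr, ev, "lever_extension", window = c(5, 5))
  expect_identical(nrow(m$aligned), 1L)
  expect_equal(m$rel_time_s[which.max(m$aligned[1, ])], 0)

  # two events over identical local signal give identical rows
  tr2 <- impulse_trace(at = c(50, 120))
  ev2 <- data.frame(event_type = "x", time_s = c(50, 120),
                    trial_index = 1:2)
  m2 <- align_to_events(tr2, ev2, "x", window = c(5, 5))
  expect_identical(m2$aligned[1, ], m2$aligned[2, ])

  # event too close to the session start is dropped and counted
  ev3 <- data.frame(event_type = "x", time_s = c(2, 100), trial_index = 1:2)
  m3 <- align_to_events(tr, ev3, "x", window = c(5, 5))
  expect_identical(nrow(m3$aligned), 1L)
  expect_identical(m3$n_dropped, 1L)

  expect_error(align_to_events(tr, ev, "nonexistent"),
               class = "striatr_empty_alignment")
})

test_that("baseline_correct subtracts the ITI mean exactly", {
  tr <- impulse_trace()
  ev <- data.frame(event_type = "x", time_s = c(50, 100, 150),
                   trial_index = 1:3)
  m <- align_to_events(tr, ev, "x", window = c(5, 5))
  m$aligned[1, ] <- 3                      # constant row -> zero
  m$aligned[2, ] <- 1                      # baseline 1 + step of 4
  m$aligned[2, m$rel_time_s >= 0] <- 5
  mc <- baseline_correct(m)
  expect_true(all(abs(mc$aligned[1, ]) < 1e-12))
  expect_equal(unname(mc$aligned[2, mc$rel_time_s >= 0][1]), 4)
  bsel <- mc$rel_time_s >= -5 & mc$rel_time_s <= -0.5
  expect_lt(max(abs(rowMeans(mc$aligned[, bsel]))), 1e-12)

  expect_error(baseline_correct(m, window = c(-50, -40)),
               class = "striatr_invalid_window")
})

test_that("event_metrics: rectangle AUC oracle, windows, flat trace", {
  fs <- 20
  tr <- impulse_trace(n = 4000, fs = fs, at = numeric())
  ev <- data.frame(event_type = "lever_extension", time_s = 100,
                   trial_index = 1L)
  m <- align_to_events(tr, ev, "lever_extension", window = c(5, 5))
  # rectangular pulse of height 2 covering exactly [0, 1.5] s
  m$aligned[1, m$rel_time_s >= 0 & m$rel_time_s <= 1.5] <- 2
  mc <- baseline_correct(m)
  em <- event_metrics(mc)
  # trapezoid loses half a sample at each edge of the discrete rectangle
  expect_equal(em$auc, 2 * 1.5, tolerance = 2 / fs)
  expect_equal(em$peak_height, 2)

  em2 <- event_metrics(mc, window = c(0, 1.0))
  expect_equal(em2$auc, 2 * 1.0, tolerance = 2 / fs)

  # flat zero trace: zero AUC, absent peak
  m0 <- baseline_correct(align_to_events(tr, ev, "lever_extension",
                                         window = c(5, 5)))
  em0 <- event_metrics(m0)
  expect_equal(em0$auc, 0)
  expect_true(is.na(em0$peak_height))

  expect_error(event_metrics(mc, event_type = "mystery_event"),
               class = "striatr_configuration_error")
})

test_that("AUC of the trial average equals the average of per-trial AUCs", {
  set.seed(21)
  tr <- random_smooth_trace(6000, fs = 20, seed = 21)
  ev <- data.frame(event_type = "x", time_s = c(60, 120, 180, 240),
                   trial_index = 1:4)
  m <- baseline_correct(align_to_events(tr, ev, "x", window = c(5, 5)))
  em <- event_metrics(m, window = c(0, 3))
  expect_equal(em$auc, mean(em$auc_per_trial), tolerance = 1e-10)
})

test_that("detect_spontaneous: threshold behavior and constructed transients", {
  fs <- 20
  n <- 6000
  t <- (seq_len(n) - 1) / fs
  # noiseless construction: a slow sine sets the session SD (~1); narrow
  # bumps of height ~1, 3, 5 session-SD ride on monotonic stretches of it,
  # so each bump's prominence within its ITI span is ~its height
  base <- sqrt(2) * sin(2 * pi * t / 300)
  kern <- function(at, h) h * exp(-((t - at)^2) / (2 * 0.1^2))
  z3 <- base + kern(120, 1) + kern(200, 3) + kern(250, 5)
  s_sd <- sqrt(mean((z3 - mean(z3))^2))
  expect_equal(s_sd, 1, tolerance = 0.05)
  tr <- dff_trace(t, z3, zdff = z3, session_mean = 0, session_sd = 1, fs = fs)
  det <- detect_spontaneous(tr, list(c(110, 130), c(190, 210), c(240, 260)))
  expect_identical(nrow(det), 2L)  # the ~1 SD bump falls below 2 SD
  expect_equal(det$peak_time_s, c(200, 250), tolerance = 0.1)
  expect_true(all(det$prominence > 2 * s_sd))
  # widths ~FWHM of the Gaussian bump (0.235 s), shifted a little by the
  # underlying sine slope
  expect_true(all(det$width_s > 0.15 & det$width_s < 0.45))

  # no spans -> empty result
  expect_identical(nrow(detect_spontaneous(tr, list())), 0L)

  # events lie inside their spans
  expect_true(all(det$peak_time_s >= 190 & det$peak_time_s <= 260))
})

test_that("detector equals the exhaustive prominence oracle", {
  for (seed in 1:8) {
    tr <- random_smooth_trace(2000, fs = 20, seed = seed)
    span <- list(c(5, 95))
    det <- detect_spontaneous(tr, span, threshold_sd = 2)
    sel <- which(tr$time_s >= 5 & tr$time_s <= 95)
    orc <- oracle_peaks(tr$zdff[sel])
    s_sd <- sqrt(mean((tr$zdff - mean(tr$zdff))^2))
    orc <- orc[orc$prominence > 2 * s_sd, ]
    expect_equal(det$peak_time_s, tr$time_s[sel][orc$index])
    expect_equal(det$prominence, orc$prominence)
    expect_equal(det$amplitude, orc$value)
  }
})

test_that("height mode applies the alternative threshold reading", {
  tr <- random_smooth_trace(2000, fs = 20, seed = 3)
  span <- list(c(5, 95))
  det_h <- detect_spontaneous(tr, span, mode = "height")
  z <- tr$zdff
  thr <- mean(z) + 2 * sqrt(mean((z - mean(z))^2))
  expect_true(all(det_h$amplitude > thr))
})

test_that("amphetamine metrics recover logistic ground truth", {
  am <- simulate_amphetamine_session(duration = 3600, injection_time_s = 1800,
                                     plateau = 8, rise_rate = 0.01,
                                     midpoint_s = 300, noise_sd = 0)
  met <- amphetamine_metrics(am, 1800, 1700)
  # analytic 95% crossing of the logistic: midpoint + log(19)/rate
  t95 <- 300 + log(19) / 0.01
  expect_true(met$plateau_reached)
  expect_lt(abs(met$latency_to_plateau_s - t95), 60)  # one smoothing window
  expect_equal(met$mean_dff, mean(am$zdff[am$time_s > 1800 &
                                          am$time_s <= 3500]))

  # linear ramp: exact OLS slope recovery
  fs <- 10
  t <- (0:(3600 * fs - 1)) / fs
  z <- pmax(0, (t - 1800)) * 0.01
  ramp <- dff_trace(t, z, zdff = z, session_mean = 0, session_sd = 1, fs = fs)
  mr <- amphetamine_metrics(ramp, 1800, 1700)
  expect_false(mr$plateau_reached)  # keeps rising, never sustains 95% early
  expect_equal(mr$slope, 0.01, tolerance = 1e-6)

  # flat zero trace post injection
  z0 <- dff_trace(t, numeric(length(t)), zdff = numeric(length(t)),
                  session_mean = 0, session_sd = 1, fs = fs)
  m0 <- amphetamine_metrics(z0, 1800, 1700)
  expect_equal(m0$mean_dff, 0)

  expect_error(amphetamine_metrics(am, 1800, 1e5),
               class = "striatr_invalid_window")
})

test_that("correlate_metric_latency: exact, null and degenerate cases", {
  auc <- c(1, 2, 3, 4, 5)
  expect_equal(correlate_metric_latency(auc, -auc)$r, -1)

  set.seed(77)
  r <- correlate_metric_latency(rnorm(1000), rnorm(1000))
  expect_lt(abs(r$r), 0.1)
  expect_identical(r$n, 1000L)

  const <- correlate_metric_latency(auc, rep(2, 5))
  expect_true(is.na(const$r))
  expect_identical(const$flag, "zero_variance")

  # missing latencies dropped; too few pairs is an error
  expect_identical(correlate_metric_latency(1:5, c(1, 2, NA, 4, 5))$n, 4L)
  expect_error(correlate_metric_latency(1:3, c(1, NA, NA)),
               class = "striatr_insufficient_data")
})

test_that("per-trial AUC tracks injected transient amplitude (SNR >= 5)", {
  set.seed(90)
  n_tr <- 40
  times <- 30 + (0:(n_tr - 1)) * 15
  amps <- runif(n_tr, 2, 10)
  # dFF noise sd after correction ~ 100*noise/F; choose noise for SNR ~ 5
  # relative to the weakest transient at the downsampled rate
  tr <- photometry_truth(transient_times = times, transient_amplitudes = amps,
                         noise_sd = 0.5, seed = 91L)
  rec <- simulate_photometry(tr, duration = max(times) + 30, fs = 203.4)
  z <- process_photometry(rec, factor = 2)
  ev <- data.frame(event_type = "transient", time_s = times,
                   trial_index = seq_len(n_tr))
  m <- baseline_correct(align_to_events(z, ev, "transient", window = c(5, 5)))
  em <- event_metrics(m, window = c(0, 3))
  expect_gt(cor(em$auc_per_trial, amps), 0.95)
})
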