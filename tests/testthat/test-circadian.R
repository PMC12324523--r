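test_that("bin_hourly: means, conservation, shape", {
  a <- simulate_activity(amplitude = 0, noise_sd = 0, baseline = 0.2,
                         n_days = 3)
  m <- bin_hourly(a)
  expect_identical(dim(m), c(24L, 3L))
  expect_true(all(m == 0.2))

  a2 <- simulate_activity(n_days = 2, noise_sd = 0.03, seed = 4L)
  m2 <- bin_hourly(a2)
  # first bin = mean of the first 6 ten-minute epochs
  expect_equal(m2[1, 1], mean(a2$activity[1:6]))
  # total conservation under the mean identity
  expect_equal(sum(m2) * 6, sum(a2$activity))
})

test_that("interdaily stability: limits, null level, affine invariance", {
  # perfect 24-h periodic trace, any waveform
  per <- simulate_activity(n_days = 5, noise_sd = 0, waveform = "square")
  expect_equal(interdaily_stability(per), 1, tolerance = 1e-12)

  # i.i.d. noise: E[IS] ~ p/N; at 24 days of hourly epochs that is 1/24
  set.seed(10)
  noise <- activity_series((0:575) * 3600,
                           pmin(pmax(rnorm(576, 0.15, 0.03), 0), 0.3),
                           epoch_s = 3600)
  expect_lt(abs(interdaily_stability(noise) - 1 / 24), 0.03)

  # affine invariance
  a <- simulate_activity(n_days = 4, noise_sd = 0.02, seed = 2L)
  b <- a
  b$activity <- 0.5 * a$activity + 0.01
  expect_equal(interdaily_stability(a), interdaily_stability(b),
               tolerance = 1e-12)

  # zero-variance series is flagged undefined
  flat <- activity_series((0:287) * 600, rep(0.1, 288))
  expect_warning(is_flat <- interdaily_stability(flat), "undefined")
  expect_true(is.na(is_flat))
})

test_that("intradaily variability: sine and noise limits, affine invariance", {
  # noiseless hourly-binned 24-h sine: IV = 2*(1 - cos(2*pi/24)) analytically
  sine <- simulate_activity(n_days = 5, noise_sd = 0)
  expect_equal(intradaily_variability(sine), 2 * (1 - cos(2 * pi / 24)),
               tolerance = 0.01)
  expect_lt(intradaily_variability(sine), 0.07)

  # fine sampling drives IV toward 0
  fine <- simulate_activity(n_days = 5, epochs_per_day = 1440, noise_sd = 0)
  expect_lt(intradaily_variability(fine, bin = "epoch"), 1e-3)

  # i.i.d. Gaussian epochs: IV -> 2 (checked at the epoch level, N = 10000)
  set.seed(11)
  g <- activity_series((0:9999) * 600, pmin(pmax(rnorm(1e4, 0.15, 0.02), 0), 0.3))
  expect_lt(abs(intradaily_variability(g, bin = "epoch") - 2), 0.05)

  a <- simulate_activity(n_days = 4, noise_sd = 0.02, seed = 2L)
  b <- a
  b$activity <- 2 * a$activity + 0.005
  expect_equal(intradaily_variability(a), intradaily_variability(b),
               tolerance = 1e-12)
})

test_that("IS/IV agree with brute-force definitional oracles", {
  for (seed in 1:10) {
    a <- simulate_activity(n_days = 3, noise_sd = 0.04,
                           phase_jitter_sd = seed / 5, seed = seed)
    x <- as.numeric(bin_hourly(a))
    expect_equal(interdaily_stability(a), oracle_is(x, 24), tolerance = 1e-12)
    expect_equal(intradaily_variability(a), oracle_iv(x), tolerance = 1e-12)
  }
})

test_that("IS and IV stay in range and respond to jitter/noise as expected", {
  is_vals <- iv_vals <- numeric()
  for (seed in 1:30) {
    a <- simulate_activity(n_days = 3, noise_sd = runif(1, 0, 0.1),
                           phase_jitter_sd = runif(1, 0, 4), seed = seed)
    is_vals <- c(is_vals, interdaily_stability(a))
    iv_vals <- c(iv_vals, intradaily_variability(a))
  }
  expect_true(all(is_vals >= 0 & is_vals <= 1 + 1e-12))
  expect_true(all(iv_vals >= 0))

  # monotone trends in expectation: more day-to-day phase jitter -> lower
  # IS; more white noise -> higher IV (averaged over seeds)
  mean_is <- function(j) mean(sapply(1:10, function(s)
    interdaily_stability(simulate_activity(n_days = 4, noise_sd = 0.02,
                                           phase_jitter_sd = j, seed = s))))
  expect_gt(mean_is(0), mean_is(3))
  mean_iv <- function(ns) mean(sapply(1:10, function(s)
    intradaily_variability(simulate_activity(n_days = 4, noise_sd = ns,
                                             seed = s))))
  expect_gt(mean_iv(0.1), mean_iv(0.01))
})

test_that("phase summaries: sleep percentages and bout structure", {
  # all-asleep series: 100% in both phases, one bout per phase per day
  n_days <- 3
  s_all <- activity_series((0:(144 * n_days - 1)) * 600,
                           rep(0.01, 144 * n_days),
                           sleep_state = rep(1L, 144 * n_days))
  ph <- phase_summary(s_all)
  expect_equal(ph$pct_time_asleep, c(100, 100))
  expect_equal(ph["light", "n_bouts"] + ph["dark", "n_bouts"], 2 * n_days)
  expect_equal(ph["light", "mean_bout_length_s"], 12 * 3600)

  # alternating sleep/wake: mean bout length = one epoch (600 s)
  alt <- activity_series((0:287) * 600, rep(c(0.01, 0.2), 144),
                         sleep_state = rep(c(1L, 0L), 144))
  ph_alt <- phase_summary(alt)
  expect_equal(ph_alt["light", "mean_bout_length_s"], 600)
  expect_equal(ph_alt$pct_time_asleep, c(50, 50))

  # sleep only in light phase -> dark percentage 0
  zt <- ((0:287) * 600 / 3600) %% 24
  st <- as.integer(zt < 12)
  s_light <- activity_series((0:287) * 600, rep(0.1, 288), sleep_state = st)
  ph_l <- phase_summary(s_light)
  expect_equal(ph_l["dark", "pct_time_asleep"], 0)
  expect_equal(ph_l["light", "pct_time_asleep"], 100)

  # onset rule assigns a boundary-spanning bout wholly to its start phase
  st2 <- as.integer(zt >= 10 & zt < 14)  # bouts spanning light->dark
  s_span <- activity_series((0:287) * 600, rep(0.1, 288), sleep_state = st2)
  split_ph <- phase_summary(s_span, boundary = "split")
  onset_ph <- phase_summary(s_span, boundary = "onset")
  expect_identical(split_ph["dark", "n_bouts"], 2L)
  expect_identical(onset_ph["dark", "n_bouts"], 0L)
  expect_equal(onset_ph["light", "mean_bout_length_s"], 4 * 3600)

  # activity amplitude = mean activity over awake epochs
  expect_equal(ph_alt["light", "activity_amplitude"], 0.2)
})
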