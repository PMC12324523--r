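make_session <- function(trial_specs, schedule = "CRF", fi = NA_real_) {
  # trial_specs: list of lists(ext, presses, dip, he, dn)
  rows <- list()
  for (i in seq_along(trial_specs)) {
    ts <- trial_specs[[i]]
    add <- function(type, times) {
      for (tt in times)
        rows[[length(rows) + 1L]] <<- data.frame(event_type = type,
                                                 time_s = tt, trial_index = i)
    }
    add("lever_extension", ts$ext)
    add("lever_press", ts$presses)
    add("dipper_up", ts$dip)
    add("head_entry", ts$he)
    add("dipper_down", ts$dn)
  }
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$time_s), ]
  operant_session(ev, schedule = schedule, fixed_interval_s = fi)
}

test_that("crf_metrics: hand-counted session", {
  # 10 trials: 9 pressed, 6 consumed
  specs <- lapply(0:9, function(k) {
    base <- k * 100
    pressed <- k < 9
    consumed <- k < 6
    list(ext = base,
         presses = if (pressed) base + 42 else numeric(),
         dip = if (pressed) base + 42 else numeric(),
         he = if (consumed) base + 43.5 else numeric(),
         dn = if (pressed) base + 47 else numeric())
  })
  s <- make_session(specs)
  m <- crf_metrics(s)
  expect_equal(m$pct_lever_press, 90)
  expect_equal(m$pct_rewarded_trials, 60)
  expect_equal(m$latency_first_press_s, 42)
  expect_equal(m$latency_reward_s, 1.5)
  expect_identical(m$total_presses, 9L)
  expect_identical(m$n_missing_press, 1L)

  expect_error(fi_metrics(s), class = "striatr_schedule_mismatch")
})

test_that("fi_metrics: interval rule and missing-press bookkeeping", {
  # interval 2 s: presses at 0.5/1.0/2.5 after extension; reward at 2.5
  s <- make_session(list(
    list(ext = 0, presses = c(0.5, 1.0, 2.5), dip = 2.5, he = 3.0, dn = 12.5),
    list(ext = 30, presses = numeric(), dip = numeric(), he = numeric(),
         dn = numeric())),
    schedule = "FI", fi = 2)
  m <- fi_metrics(s)
  expect_identical(m$total_presses, 3L)
  expect_equal(m$pct_lever_press, 50)
  expect_equal(m$latency_first_press_s, 0.5)
  expect_equal(m$latency_mean_press_s, mean(c(0.5, 1.0, 2.5)))
  expect_equal(m$latency_reward_s, 0.5)
  expect_identical(m$n_missing_press, 1L)

  # first-press averaging mode
  expect_equal(fi_metrics(s, mean_press_over = "first")$latency_mean_press_s,
               0.5)
})

test_that("operant metrics equal brute-force recounts on random sessions", {
  for (seed in 1:60) {
    sched <- if (seed %% 2) "CRF" else "FI"
    spec <- if (sched == "CRF")
      schedule_spec("CRF", n_trials = 8)
    else schedule_spec("FI", fixed_interval = sample(c(2, 4, 8, 12, 24), 1),
                       n_trials = 8)
    s <- simulate_event_schedule(spec, p_engage = 0.8, seed = seed)
    m <- if (sched == "CRF") crf_metrics(s) else fi_metrics(s)
    o <- oracle_operant(s)
    for (f in names(o)) expect_equal(m[[f]], o[[f]], tolerance = 1e-12,
                                     label = sprintf("%s (seed %d)", f, seed))
    expect_lte(m$pct_rewarded_trials, m$pct_lever_press)
  }
})

test_that("scallop_curve: conservation, uniform null, rising profile", {
  spec <- schedule_spec("FI", fixed_interval = 8, n_trials = 40,
                        press_rate_profile = function(u) rep(0.5, length(u)))
  s <- simulate_event_schedule(spec, seed = 13L)
  sc <- scallop_curve(s, n_bins = 4)
  # conservation: sum(rate * trials * bin duration) = in-interval presses
  in_int <- sum(sc$n_presses)
  expect_equal(sum(sc$rate_hz * 40 * 2), in_int)
  # uniform process: flat within Poisson error (chi-square on counts)
  expect_gt(stats::chisq.test(sc$n_presses)$p.value, 0.001)

  rising <- simulate_event_schedule(
    schedule_spec("FI", fixed_interval = 8, n_trials = 40,
                  press_rate_profile = function(u) u),
    rate_scale = 2, seed = 14L)
  scr <- scallop_curve(rising, n_bins = 4)
  slope <- coef(lm(scr$rate_hz ~ scr$bin_start_s))[2]
  expect_gt(slope, 0)

  # single bin equals overall in-interval rate
  sc1 <- scallop_curve(s, n_bins = 1)
  expect_equal(sc1$rate_hz, in_int / (40 * 8))

  # zero in-interval rate: all-zero flagged curve (the rewarded press falls
  # after the interval, outside the scallop window)
  none <- simulate_event_schedule(
    schedule_spec("FI", fixed_interval = 4, n_trials = 5,
                  press_rate_profile = function(u) 0 * u),
    latency_model = list(type = "deterministic", value = 1), seed = 1L)
  sc0 <- scallop_curve(none, n_bins = 3)
  expect_true(all(sc0$rate_hz == 0))
  expect_identical(attr(sc0, "flag"), "no_presses")
})

test_that("FI first-press latency grows with the interval (scaled rates)", {
  mean_lat <- function(fi) {
    vals <- sapply(1:6, function(s) {
      sess <- simulate_event_schedule(
        schedule_spec("FI", fixed_interval = fi, n_trials = 20),
        latency_model = list(type = "exponential", mean = 2),
        rate_scale = 4 / fi, seed = s)
      fi_metrics(sess)$latency_first_press_s
    })
    mean(vals)
  }
  expect_gt(mean_lat(24), mean_lat(2))
})

test_that("lick_metrics: counts, latencies, per-concentration restriction", {
  log <- simulate_lick_session(30, p_engage = 0.8, seed = 3L)
  m <- lick_metrics(log)
  gt <- ground_truth(log)
  expect_identical(m$n_completed, sum(gt$engaged))
  expect_identical(m$n_completed + m$n_incomplete, m$n_trials_presented)
  expect_identical(m$total_licks, nrow(log$licks))

  # per-concentration means use completed trials only; a concentration with
  # no completed trials is NA, not zero
  trials <- data.frame(trial_index = 1:4,
                       concentration = c(0, 0, 50, 100),
                       onset_s = c(0, 25, 50, 75))
  licks <- data.frame(trial_index = c(1, 1, 1, 3), time_s = c(1, 2, 3, 51))
  m2 <- lick_metrics(lick_log(trials, licks))
  expect_equal(unname(m2$licks_by_concentration["0"]), 3)    # trial 2 excluded
  expect_equal(unname(m2$licks_by_concentration["50"]), 1)
  expect_true(is.na(m2$licks_by_concentration["100"]))
  expect_equal(m2$latency_first_lick_s, mean(c(1, 1)))

  # all first licks at trial onset -> zero latency
  licks0 <- data.frame(trial_index = 1:4, time_s = c(0, 25, 50, 75))
  expect_equal(lick_metrics(lick_log(trials, licks0))$latency_first_lick_s, 0)
})

test_that("trough training: window rule and session sizes", {
  mk_trough <- function(he_offsets) {
    rows <- list()
    for (i in seq_along(he_offsets)) {
      base <- (i - 1) * 40
      rows[[length(rows) + 1L]] <- data.frame(
        event_type = c("dipper_up", "dipper_down"),
        time_s = c(base, base + 10), trial_index = i)
      if (!is.na(he_offsets[i]))
        rows[[length(rows) + 1L]] <- data.frame(
          event_type = "head_entry", time_s = base + he_offsets[i],
          trial_index = i)
    }
    ev <- do.call(rbind, rows)
    operant_session(ev[order(ev$time_s), ], schedule = "trough")
  }
  # 30 presentations all retrieved
  expect_equal(trough_training_metrics(mk_trough(rep(2, 30)))$pct_retrieved,
               100)
  # head entry 11 s after dipper_up (dipper already down) is not counted
  m <- trough_training_metrics(mk_trough(c(2, 11, NA)))
  expect_equal(m$pct_retrieved, 100 / 3)
  # later sessions with 60 presentations are accepted
  expect_identical(trough_training_metrics(mk_trough(rep(1, 60)))$n_presented,
                   60L)
})
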