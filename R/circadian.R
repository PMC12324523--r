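# Nonparametric rest-activity statistics from epoch-binned piezo data:
# hourly binning, interdaily stability (IS), intradaily variability (IV)
# and light/dark phase summaries.
#
# Standard actigraphy definitions on binned data x_1..x_N with p bins per
# day and per-bin-of-day means xbar_h:
#   IS = (N * sum_h (xbar_h - xbar)^2) / (p * sum_i (x_i - xbar)^2)
#   IV = (N * sum_{i>=2} (x_i - x_{i-1})^2) / ((N - 1) * sum_i (x_i - xbar)^2)
# IS is 1 for a trace perfectly locked to a 24-h zeitgeber and about 1/p for
# exchangeable noise; IV converges to 0 for a smooth sine and to 2 for
# Gaussian white noise.

zt_hours <- function(s) s$start_zt_h + s$epoch_start_s / 3600

#' Bin an activity series into hourly means by zeitgeber hour and day
#'
#' @param s An [activity_series()].
#' @return A 24 x n_days matrix of hourly mean activity (rows = ZT hour
#'   0-23, columns = day).
#' @export
bin_hourly <- function(s) {
  if (!inherits(s, "activity_series"))
    abort_striatr("s must be an activity_series", "striatr_invalid_parameter")
  per_hour <- 3600 / s$epoch_s
  if (abs(per_hour - round(per_hour)) > 1e-9)
    abort_striatr("epochs must divide hours evenly",
                  "striatr_invalid_parameter")
  zh <- floor(zt_hours(s) + 1e-9)
  day <- zh %/% 24
  hour <- zh %% 24
  n_days <- max(day) + 1L
  out <- matrix(NA_real_, nrow = 24, ncol = n_days,
                dimnames = list(zt_hour = 0:23, day = seq_len(n_days)))
  agg <- tapply(s$activity, list(factor(hour, levels = 0:23),
                                 factor(day, levels = 0:(n_days - 1L))),
                mean)
  out[, ] <- agg
  out
}

# Binned vector for IS/IV with incomplete days dropped wholesale.
binned_values <- function(s, bin = c("hourly", "epoch")) {
  bin <- match.arg(bin)
  if (bin == "hourly") {
    m <- bin_hourly(s)
    complete <- colSums(is.na(m)) == 0
    if (sum(complete) < 2)
      abort_striatr("need >= 2 complete days", "striatr_invalid_parameter")
    as.numeric(m[, complete])
  } else {
    per_day <- 86400 / s$epoch_s
    n_days <- floor(length(s$activity) / per_day)
    if (n_days < 2)
      abort_striatr("need >= 2 complete days", "striatr_invalid_parameter")
    s$activity[seq_len(n_days * per_day)]
  }
}

bins_per_day <- function(s, bin) if (bin == "hourly") 24 else 86400 / s$epoch_s

#' Interdaily stability
#'
#' Quantifies how consistently the activity profile repeats from day to day;
#' 1 indicates perfect coupling to a 24-hour zeitgeber, values near `1/p`
#' (1/24 on hourly bins) indicate no day structure. Invariant to affine
#' transforms of activity.
#'
#' @param s An [activity_series()] covering at least 2 complete days.
#' @param bin `"hourly"` (default, the standard choice) or `"epoch"`.
#' @return IS in \[0, 1\], or `NA` (flagged by warning) for zero variance.
#' @export
interdaily_stability <- function(s, bin = c("hourly", "epoch")) {
  bin <- match.arg(bin)
  x <- binned_values(s, bin)
  p <- bins_per_day(s, bin)
  N <- length(x)
  xbar <- mean(x)
  denom <- sum((x - xbar)^2)
  if (denom == 0) {
    warning("zero total variance: interdaily stability undefined")
    return(NA_real_)
  }
  h <- (seq_len(N) - 1) %% p
  hbar <- tapply(x, h, mean)
  N * sum((hbar - xbar)^2) / (p * denom)
}

#' Intradaily variability
#'
#' Quantifies fragmentation of the rest-activity pattern as the normalized
#' mean square of successive differences; converges to 0 for a smooth
#' sinusoid (analytically `2 * (1 - cos(2 * pi / p))` for a 24-h sine
#' sampled at `p` bins/day) and approaches 2 for Gaussian white noise.
#' Invariant to affine transforms of activity.
#'
#' @inheritParams interdaily_stability
#' @return IV >= 0, or `NA` (flagged by warning) for zero variance.
#' @export
intradaily_variability <- function(s, bin = c("hourly", "epoch")) {
  bin <- match.arg(bin)
  x <- binned_values(s, bin)
  N <- length(x)
  xbar <- mean(x)
  denom <- sum((x - xbar)^2)
  if (denom == 0) {
    warning("zero total variance: intradaily variability undefined")
    return(NA_real_)
  }
  N * sum(diff(x)^2) / ((N - 1) * denom)
}

#' Light/dark phase summaries of sleep and activity
#'
#' Splits epochs into light (ZT 0-12) and dark (ZT 12-24) phases of the
#' 12:12 schedule and reports, per phase: percent of time asleep, mean
#' sleep-bout duration, mean activity, and activity amplitude (mean
#' activity over awake epochs). Sleep bouts are maximal runs of
#' `sleep_state == 1`; by default a bout spanning a light/dark boundary is
#' split at the boundary and counted in both phases
#' (`boundary = "onset"` instead assigns the whole bout to the phase it
#' started in).
#'
#' @param s An [activity_series()] with `sleep_state` populated.
#' @param boundary `"split"` (default) or `"onset"`.
#' @return A `data.frame` with rows `light` and `dark` and columns
#'   `phase`, `pct_time_asleep`, `mean_bout_length_s`, `mean_activity`,
#'   `activity_amplitude`, `n_bouts`.
#' @export
phase_summary <- function(s, boundary = c("split", "onset")) {
  boundary <- match.arg(boundary)
  if (!inherits(s, "activity_series"))
    abort_striatr("s must be an activity_series", "striatr_invalid_parameter")
  if (anyNA(s$sleep_state))
    abort_striatr("sleep_state must be populated", "striatr_invalid_parameter")
  zt <- zt_hours(s) %% 24
  dark <- zt >= 12
  phase <- ifelse(dark, "dark", "light")

  bout_lengths <- function(keep_phase) {
    sel_sleep <- s$sleep_state == 1L
    if (boundary == "split") {
      grp_sleep <- sel_sleep & (phase == keep_phase)
      r <- rle(grp_sleep)
      r$lengths[r$values] * s$epoch_s
    } else {
      r <- rle(sel_sleep)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values & phase[starts] == keep_phase
      r$lengths[keep] * s$epoch_s
    }
  }

  summ <- lapply(c("light", "dark"), function(ph) {
    in_ph <- phase == ph
    asleep <- s$sleep_state[in_ph] == 1L
    awake_act <- s$activity[in_ph][!asleep]
    bl <- bout_lengths(ph)
    data.frame(
      phase = ph,
      pct_time_asleep = 100 * mean(asleep),
      mean_bout_length_s = if (length(bl)) mean(bl) else NA_real_,
      mean_activity = mean(s$activity[in_ph]),
      activity_amplitude = if (length(awake_act)) mean(awake_act)
                           else NA_real_,
      n_bouts = length(bl))
  })
  out <- do.call(rbind, summ)
  rownames(out) <- out$phase
  out
}
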