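# Synthetic rest-activity data emulating piezo floor-sensor output:
# normalized movement intensity per 10-min epoch scaled to [0, 0.3], with a
# nocturnal (dark-phase) activity rhythm under a 12:12 light/dark schedule.

#' Simulate an epoch-binned activity series
#'
#' Activity = `baseline + amplitude * periodic(t) + noise`, clipped to
#' \[0, 0.3\]. The periodic component peaks at mid-dark (ZT18) to emulate a
#' nocturnal rodent; the recording starts at lights-on (ZT0). A companion
#' sleep/wake state is derived by thresholding activity at the series
#' midline, and day-to-day phase jitter can be injected to degrade
#' interdaily stability in a controlled way.
#'
#' @param amplitude Rhythm amplitude, a.u.
#' @param period Rhythm period, hours (24 for a zeitgeber-locked rhythm).
#' @param epochs_per_day Epochs per 24 h (>= 24); 144 gives the standard
#'   10-min epochs.
#' @param n_days Number of recorded days (>= 2).
#' @param noise_sd Additive Gaussian noise SD, a.u.
#' @param light_on Clock hour of lights-on (default 6).
#' @param baseline Mean activity level, a.u.
#' @param waveform `"sine"` for a sinusoidal rhythm or `"square"` for a
#'   light/dark step profile.
#' @param phase_jitter_sd Day-to-day SD of a random phase shift, hours.
#' @param seed Integer seed.
#' @return An [activity_series()] carrying ground truth.
#' @export
#' @examples
#' act <- simulate_activity(n_days = 5, noise_sd = 0)
simulate_activity <- function(amplitude = 0.1, period = 24,
                              epochs_per_day = 144, n_days = 5,
                              noise_sd = 0.02, light_on = 6,
                              baseline = 0.15,
                              waveform = c("sine", "square"),
                              phase_jitter_sd = 0, seed = 1L) {
  waveform <- match.arg(waveform)
  if (epochs_per_day < 24)
    abort_striatr("epochs_per_day must be >= 24", "striatr_invalid_parameter")
  if (n_days < 2)
    abort_striatr("n_days must be >= 2", "striatr_invalid_parameter")
  if (amplitude < 0 || noise_sd < 0)
    abort_striatr("amplitude and noise_sd must be >= 0",
                  "striatr_invalid_parameter")

  epoch_s <- 86400 / epochs_per_day
  n <- epochs_per_day * n_days
  start_s <- (seq_len(n) - 1) * epoch_s
  zt_h <- (start_s + epoch_s / 2) / 3600  # epoch midpoints, hours since ZT0

  with_seed(seed, {
    day <- floor(zt_h / 24)
    shift <- if (phase_jitter_sd > 0)
      stats::rnorm(n_days, 0, phase_jitter_sd)[day + 1] else 0
    ph <- zt_h + shift
    periodic <- switch(waveform,
      sine = cos(2 * pi * (ph - 18) / period),
      square = ifelse((ph %% period) >= period / 2, 1, -1))
    act <- baseline + amplitude * periodic + stats::rnorm(n, 0, noise_sd)
  })
  act <- pmin(pmax(act, 0), 0.3)

  # Asleep when activity falls below the series midline: captures the
  # light-phase (rest) bias of a nocturnal rhythm.
  thr <- (max(act) + min(act)) / 2
  sleep <- as.integer(act < thr)

  s <- activity_series(start_s, act, sleep_state = sleep, epoch_s = epoch_s,
                       light_on = light_on, start_zt_h = 0)
  attr(s, "ground_truth") <- list(
    amplitude = amplitude, period = period, epochs_per_day = epochs_per_day,
    n_days = n_days, noise_sd = noise_sd, baseline = baseline,
    waveform = waveform, phase_jitter_sd = phase_jitter_sd, seed = seed)
  s
}
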