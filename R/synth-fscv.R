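# Synthetic FSCV transients. Only the extracted transient time course is
# simulated (one concentration value per voltammogram, so the natural rate
# is 10 Hz for a waveform repeated every 100 ms); the voltammogram sweep
# itself is out of scope.

#' Simulate a stimulated FSCV dopamine transient
#'
#' The trace sits at a flat baseline, ramps linearly to its peak over
#' `rise_s` after the stimulus, then decays as a single exponential
#' `imax * exp(-(t - t_peak)/tau1)` — the clearance model whose time
#' constant Tau1 is the reuptake readout.
#'
#' @param imax Peak amplitude above baseline, uM (> 0).
#' @param tau1 Clearance time constant, milliseconds (> 0).
#' @param stim_time Stimulation time, seconds.
#' @param duration Trace length, seconds.
#' @param fs Sampling rate, Hz; default 10 Hz (one voltammogram per 100 ms).
#' @param baseline Baseline level, uM.
#' @param rise_s Rise time from stimulus to peak, seconds.
#' @param noise_sd Additive white-noise SD, uM.
#' @param calibration_factor If supplied (uM per pA), the trace is emitted in
#'   raw pA (`value = uM / calibration_factor`) for exercising [calibrate_fscv()];
#'   otherwise the trace is already in uM.
#' @param seed Integer seed.
#' @return An [fscv_trace()] carrying ground truth.
#' @export
#' @examples
#' tr <- simulate_fscv_sweep(imax = 1, tau1 = 500, stim_time = 5)
simulate_fscv_sweep <- function(imax, tau1, stim_time = 5, duration = 15,
                                fs = 10, baseline = 0, rise_s = 0.2,
                                noise_sd = 0, calibration_factor = NULL,
                                seed = 1L) {
  stopifnot_scalar_number(imax, "imax", positive = TRUE)
  stopifnot_scalar_number(tau1, "tau1", positive = TRUE)
  stopifnot_scalar_number(stim_time, "stim_time")
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  n <- floor(duration * fs)
  t <- (seq_len(n) - 1) / fs
  t_peak <- stim_time + rise_s
  tau_s <- tau1 / 1000

  v <- rep(baseline, n)
  rising <- t > stim_time & t < t_peak
  v[rising] <- baseline + imax * (t[rising] - stim_time) / rise_s
  decaying <- t >= t_peak
  v[decaying] <- baseline + imax * exp(-(t[decaying] - t_peak) / tau_s)

  v <- with_seed(seed, v + stats::rnorm(n, 0, noise_sd))

  units <- "uM"
  cal <- NA_real_
  if (!is.null(calibration_factor)) {
    stopifnot_scalar_number(calibration_factor, "calibration_factor",
                            positive = TRUE)
    v <- v / calibration_factor
    units <- "pA"
    cal <- calibration_factor
  }
  tr <- fscv_trace(t, v, units = units, stim_time_s = stim_time,
                   calibration_factor = cal)
  attr(tr, "ground_truth") <- list(
    imax = imax, tau1 = tau1, stim_time = stim_time, t_peak = t_peak,
    baseline = baseline, rise_s = rise_s, noise_sd = noise_sd, seed = seed)
  tr
}
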