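# Synthetic two-channel photometry.
#
# Generative model. Both channels share a slow photobleaching envelope and
# additive motion bumps; dopamine transients appear only in the 465 nm
# channel, multiplicatively on the local fluorescence so that their size is
# stated directly in dFF percent:
#
#   ref_405(t) = B(t) + M(t) + noise
#   sig_465(t) = [g * (B(t) + M(t)) + offset] * (1 + dff_true(t)/100) + noise
#
# with B(t) a single decaying exponential, M(t) exponentially decaying bumps,
# g the channel gain and dff_true a sum of difference-of-exponential kernels.
# With zero noise and zero transients the signal channel is an exact affine
# image of the reference — the identifiability condition for the
# isosbestic regression correction.

#' Ground-truth parameter set for synthetic photometry
#'
#' @param transient_times Dopamine transient times, seconds (session clock).
#' @param transient_amplitudes Peak transient sizes in dFF percent (>= 0),
#'   recycled against `transient_times`.
#' @param kernel_rise_tau,kernel_decay_tau Rise and decay time constants of
#'   the difference-of-exponentials transient kernel, seconds. Defaults
#'   (0.1 s rise, 0.8 s decay) give sub-second peaks matching dLight
#'   dopamine-sensor kinetics.
#' @param bleach_tau Photobleaching time constant, seconds.
#' @param motion_events List of `c(time_s, amplitude_au)` motion artifacts
#'   shared by both channels.
#' @param reference_gain Multiplicative gain relating the shared structure in
#'   the signal channel to the reference channel.
#' @param signal_offset Additive offset of the signal channel, a.u.
#' @param ref_baseline Steady-state reference fluorescence, a.u.
#' @param bleach_frac Fraction of the reference baseline that bleaches away.
#' @param motion_tau Decay time constant of motion bumps, seconds.
#' @param noise_sd Additive white-noise SD per channel, a.u.
#' @param seed Integer seed; a fixed seed reproduces the output exactly.
#' @return A list of class `photometry_truth`.
#' @export
photometry_truth <- function(transient_times = numeric(),
                             transient_amplitudes = numeric(),
                             kernel_rise_tau = 0.1,
                             kernel_decay_tau = 0.8,
                             bleach_tau = 1200,
                             motion_events = list(),
                             reference_gain = 1.5,
                             signal_offset = 20,
                             ref_baseline = 100,
                             bleach_frac = 0.3,
                             motion_tau = 0.5,
                             noise_sd = 0,
                             seed = 1L) {
  stopifnot_scalar_number(kernel_rise_tau, "kernel_rise_tau", positive = TRUE)
  stopifnot_scalar_number(kernel_decay_tau, "kernel_decay_tau", positive = TRUE)
  stopifnot_scalar_number(bleach_tau, "bleach_tau", positive = TRUE)
  if (kernel_rise_tau >= kernel_decay_tau)
    abort_striatr("kernel_rise_tau must be < kernel_decay_tau",
                  "striatr_invalid_parameter")
  if (length(transient_times)) {
    transient_amplitudes <- rep_len(transient_amplitudes,
                                    length(transient_times))
    if (any(transient_amplitudes < 0))
      abort_striatr("transient amplitudes must be >= 0",
                    "striatr_invalid_parameter")
  }
  structure(
    list(transient_times = transient_times,
         transient_amplitudes = transient_amplitudes,
         kernel_rise_tau = kernel_rise_tau,
         kernel_decay_tau = kernel_decay_tau,
         bleach_tau = bleach_tau, motion_events = motion_events,
         reference_gain = reference_gain, signal_offset = signal_offset,
         ref_baseline = ref_baseline, bleach_frac = bleach_frac,
         motion_tau = motion_tau, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "photometry_truth"
  )
}

# Difference-of-exponentials kernel normalized to unit peak:
#   k(t) = (exp(-t/tau_d) - exp(-t/tau_r)) / k_max,  t >= 0.
# Peak is at t* = tau_r*tau_d/(tau_d - tau_r) * log(tau_d/tau_r).
transient_kernel <- function(t, tau_r, tau_d) {
  t_star <- tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
  k_max <- exp(-t_star / tau_d) - exp(-t_star / tau_r)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- (exp(-t[pos] / tau_d) - exp(-t[pos] / tau_r)) / k_max
  out
}

#' Simulate a two-channel fiber-photometry recording
#'
#' Generates a 465 nm signal channel and a 405 nm isosbestic reference that
#' share bleaching and motion structure, with dopamine transients injected
#' only in the signal channel at known dFF amplitudes. Ground truth
#' (including the noiseless true dFF trace) is stored on the result and
#' retrievable with [ground_truth()].
#'
#' @param truth A [photometry_truth()] parameter set.
#' @param duration Recording duration, seconds (> 0).
#' @param fs Sampling rate, Hz (> 0); acquisition hardware digitizes at
#'   1017 Hz by default.
#' @param events Optional event table to attach (defaults to one `transient`
#'   event per injected transient).
#' @return A [photometry_recording()] with a `ground_truth` attribute.
#' @export
#' @examples
#' tr <- photometry_truth(transient_times = 100, transient_amplitudes = 5)
#' rec <- simulate_photometry(tr, duration = 200, fs = 101.7)
simulate_photometry <- function(truth, duration, fs = 1017, events = NULL) {
  if (!inherits(truth, "photometry_truth"))
    abort_striatr("truth must come from photometry_truth()",
                  "striatr_invalid_parameter")
  stopifnot_scalar_number(duration, "duration", positive = TRUE)
  stopifnot_scalar_number(fs, "fs", positive = TRUE)

  n <- floor(duration * fs)
  t <- (seq_len(n) - 1) / fs

  bleach <- truth$ref_baseline *
    ((1 - truth$bleach_frac) + truth$bleach_frac * exp(-t / truth$bleach_tau))
  motion <- numeric(n)
  for (me in truth$motion_events) {
    pos <- t >= me[1]
    motion[pos] <- motion[pos] + me[2] * exp(-(t[pos] - me[1]) / truth$motion_tau)
  }

  dff_true <- numeric(n)
  for (i in seq_along(truth$transient_times)) {
    dff_true <- dff_true + truth$transient_amplitudes[i] *
      transient_kernel(t - truth$transient_times[i],
                       truth$kernel_rise_tau, truth$kernel_decay_tau)
  }

  shared <- bleach + motion
  sig_base <- truth$reference_gain * shared + truth$signal_offset

  with_seed(truth$seed, {
    ref <- shared + stats::rnorm(n, 0, truth$noise_sd)
    sig <- sig_base * (1 + dff_true / 100) + stats::rnorm(n, 0, truth$noise_sd)
  })

  if (is.null(events) && length(truth$transient_times)) {
    events <- data.frame(event_type = "transient",
                         time_s = truth$transient_times,
                         trial_index = seq_along(truth$transient_times))
  }
  rec <- photometry_recording(t, sig, ref, fs = fs, events = events)
  attr(rec, "ground_truth") <- c(unclass(truth), list(dff_true = dff_true))
  rec
}

#' Simulate an amphetamine-challenge dFF session
#'
#' After the injection the z-scored dFF follows a logistic rise to a plateau;
#' plateau level, rise rate and midpoint are the ground-truth parameters used
#' to validate the mean-dFF / slope / latency-to-plateau metrics.
#'
#' @param duration Session length, seconds.
#' @param fs Sampling rate of the (already downsampled) trace, Hz.
#' @param injection_time_s Amphetamine injection time, seconds.
#' @param plateau Plateau level, z-scored dFF units.
#' @param rise_rate Logistic rate, 1/s.
#' @param midpoint_s Time after injection at which half the plateau is
#'   reached, seconds.
#' @param noise_sd Additive white noise SD, zdFF units.
#' @param seed Integer seed.
#' @return A [dff_trace()] (with `zdff` filled) carrying ground truth.
#' @export
simulate_amphetamine_session <- function(duration = 3600, fs = 101.7 / 10,
                                         injection_time_s = 1800,
                                         plateau = 8, rise_rate = 0.01,
                                         midpoint_s = 300, noise_sd = 0,
                                         seed = 1L) {
  stopifnot_scalar_number(duration, "duration", positive = TRUE)
  stopifnot_scalar_number(rise_rate, "rise_rate", positive = TRUE)
  n <- floor(duration * fs)
  t <- (seq_len(n) - 1) / fs
  z <- plateau / (1 + exp(-rise_rate * (t - injection_time_s - midpoint_s)))
  z[t < injection_time_s] <- 0  # flat baseline before the injection
  z <- with_seed(seed, z + stats::rnorm(n, 0, noise_sd))
  tr <- dff_trace(t, dff = z, zdff = z, session_mean = 0, session_sd = 1,
                  fs = fs)
  attr(tr, "ground_truth") <- list(
    injection_time_s = injection_time_s, plateau = plateau,
    rise_rate = rise_rate, midpoint_s = midpoint_s, noise_sd = noise_sd,
    seed = seed)
  tr
}
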