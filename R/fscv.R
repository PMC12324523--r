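# Evoked dopamine transient quantification from FSCV sweeps: calibration
# against a 1 uM standard, peak amplitude (Imax) above the pre-stimulus
# baseline, and single-exponential clearance fitting (Tau1).

#' Scan rate of a symmetric triangular FSCV command waveform
#'
#' A symmetric triangle sweeps from `v_min` to `v_max` and back within
#' `sweep_duration_s`, so the scan-rate magnitude is
#' `2 * (v_max - v_min) / sweep_duration_s`. The standard dopamine waveform
#' (-450 mV to +800 mV in 8.5 ms) gives ~294 V/s.
#'
#' @param v_min,v_max Waveform limits, volts.
#' @param sweep_duration_s Time to complete the full up-and-down sweep,
#'   seconds.
#' @return Scan rate magnitude, V/s.
#' @export
#' @examples
#' fscv_scan_rate(-0.45, 0.8, 0.0085)  # ~294 V/s
fscv_scan_rate <- function(v_min = -0.45, v_max = 0.8,
                           sweep_duration_s = 0.0085) {
  stopifnot_scalar_number(sweep_duration_s, "sweep_duration_s",
                          positive = TRUE)
  if (v_max <= v_min)
    abort_striatr("v_max must exceed v_min", "striatr_invalid_parameter")
  2 * (v_max - v_min) / sweep_duration_s
}

#' Calibrate an FSCV trace from current to concentration
#'
#' Multiplies the raw current (pA) by the calibration factor (uM per pA,
#' determined from background-subtracted voltammograms of a 1 uM dopamine
#' standard) and flips the units flag. Calibrating an already-calibrated
#' trace is an explicit error to prevent double scaling.
#'
#' @param trace An [fscv_trace()] in pA.
#' @param calibration_factor uM per pA; defaults to the factor stored on the
#'   trace.
#' @return The trace in uM.
#' @export
calibrate_fscv <- function(trace,
                           calibration_factor = trace$calibration_factor) {
  if (!inherits(trace, "fscv_trace"))
    abort_striatr("trace must be an fscv_trace", "striatr_invalid_parameter")
  if (trace$units == "uM")
    abort_striatr("trace is already calibrated (uM); refusing to scale twice",
                  "striatr_already_calibrated")
  stopifnot_scalar_number(calibration_factor, "calibration_factor",
                          positive = TRUE)
  gt <- ground_truth(trace)
  trace$value <- trace$value * calibration_factor
  trace$units <- "uM"
  trace$calibration_factor <- calibration_factor
  attr(trace, "ground_truth") <- gt
  trace
}

# Bounded single-exponential fit y = b + a*exp(-(t - t0)/tau), seeded by a
# log-linear regression of (y - baseline) on t, refined by L-BFGS-B on the
# residual sum of squares with tau constrained to (1 ms, 60 s).
fit_exp_decay <- function(t, y, baseline, tau_lo = 1e-3, tau_hi = 60) {
  t <- t - t[1]
  peak <- max(y) - baseline
  # seed on the early decay (above 10% of peak) where the log transform is
  # well conditioned; noisy tail points near baseline would blow it up
  pos <- which(y - baseline > 0.1 * peak)
  if (length(pos) >= 2) {
    lf <- stats::lm.fit(cbind(1, t[pos]), log(y[pos] - baseline))
    tau0 <- -1 / lf$coefficients[2]
    a0 <- exp(lf$coefficients[1])
    if (!is.finite(tau0) || tau0 <= 0) tau0 <- diff(range(t)) / 3
    if (!is.finite(a0) || a0 <= 0 || a0 > 10 * peak) a0 <- peak
  } else {
    tau0 <- diff(range(t)) / 3
    a0 <- peak
  }
  tau0 <- min(max(tau0, tau_lo * 1.01), tau_hi * 0.99)
  sse <- function(p) {
    r <- y - (p[1] + p[2] * exp(-t / p[3]))
    sum(r * r)
  }
  fit <- stats::optim(c(baseline, a0, tau0), sse, method = "L-BFGS-B",
                      lower = c(-Inf, 1e-12, tau_lo),
                      upper = c(Inf, Inf, tau_hi),
                      control = list(maxit = 500, factr = 1e3))
  if (fit$convergence != 0 && fit$convergence != 52)
    abort_striatr(sprintf("exponential fit failed to converge (code %d: %s)",
                          fit$convergence, fit$message %||% ""),
                  "striatr_fit_failure")
  list(b = unname(fit$par[1]), a = unname(fit$par[2]),
       tau = unname(fit$par[3]), rss = fit$value)
}

#' Quantify an evoked FSCV dopamine transient
#'
#' The baseline is the mean of the 1 s window before the stimulus. Imax is
#' the maximum post-stimulus value minus that baseline (the peak must exceed
#' baseline + 3 pre-stimulus SDs, otherwise a no-transient error is
#' raised). Tau1 comes from a bounded least-squares fit of
#' `b + a * exp(-(t - t_peak)/tau)` to the decay segment starting at the
#' peak. By default the segment runs to the end of the sweep
#' (`fit_end = "sweep_end"`): the free offset `b` absorbs the baseline and
#' the post-return tail anchors it, which roughly halves the Tau1 error at
#' realistic 10 Hz sampling. `fit_end = "baseline_return"` instead truncates
#' where a 3-point running median of the trace first returns within 5
#' percent of Imax of the baseline (appropriate when the tail drifts).
#'
#' @param trace An [fscv_trace()] (pA or uM) with `stim_time_s` set.
#' @param baseline_s Pre-stimulus baseline window length, seconds.
#' @param fit_end `"sweep_end"` (default) or `"baseline_return"`.
#' @return A list of class `fscv_transient`: `imax` (trace units), `tau1`
#'   (ms), `t_peak_s`, `baseline`, `fit_rss`, `fit_window`, `units`.
#' @export
#' @examples
#' tr <- simulate_fscv_sweep(imax = 1.2, tau1 = 400, stim_time = 5)
#' quantify_transient(tr)
quantify_transient <- function(trace, baseline_s = 1,
                               fit_end = c("sweep_end", "baseline_return")) {
  fit_end <- match.arg(fit_end)
  if (!inherits(trace, "fscv_trace"))
    abort_striatr("trace must be an fscv_trace", "striatr_invalid_parameter")
  t <- trace$time_s; v <- trace$value
  pre <- which(t < trace$stim_time_s & t >= trace$stim_time_s - baseline_s)
  if (length(pre) < 2L)
    abort_striatr("need >= 1 s of pre-stimulus baseline",
                  "striatr_invalid_parameter")
  baseline <- mean(v[pre])
  pre_sd <- stats::sd(v[pre])
  post <- which(t >= trace$stim_time_s)
  pk_rel <- which.max(v[post])
  pk <- post[pk_rel]
  imax <- v[pk] - baseline
  if (imax <= 3 * pre_sd || imax <= 0)
    abort_striatr("no transient: peak does not exceed baseline + 3 SD",
                  "striatr_no_transient")

  decay <- seq.int(pk, length(t))
  if (fit_end == "baseline_return") {
    # return judged on a 3-point running median so a single downward noise
    # excursion cannot truncate the decay segment early
    v_dec <- v[decay]
    v_med <- if (length(v_dec) >= 3L) stats::runmed(v_dec, 3L) else v_dec
    ret <- which(v_med <= baseline + 0.05 * imax)
    if (length(ret)) decay <- decay[seq_len(ret[1])]
  }
  if (length(decay) < 3L)
    abort_striatr("decay segment too short to fit", "striatr_fit_failure")
  ft <- fit_exp_decay(t[decay], v[decay], baseline)

  structure(
    list(imax = imax, tau1 = ft$tau * 1000, t_peak_s = t[pk],
         baseline = baseline, fit_rss = ft$rss,
         fit_window = c(t[decay[1]], t[decay[length(decay)]]),
         units = trace$units),
    class = "fscv_transient"
  )
}

#' @export
print.fscv_transient <- function(x, ...) {
  cat(sprintf("<fscv_transient> Imax %.4g %s, Tau1 %.4g ms, peak at %.3g s\n",
              x$imax, x$units, x$tau1, x$t_peak_s))
  invisible(x)
}

#' Summarize an FSCV session by its middle three sweeps
#'
#' In the standard protocol a pulse is delivered every 2 minutes for 10
#' minutes and the three middle peaks are analyzed. Given `n >= 3` accepted
#' transients in delivery order, positions `ceiling(n/2) - 1` through
#' `ceiling(n/2) + 1` are selected (ties on even counts resolved toward the
#' earlier sweeps) and their mean Imax and Tau1 reported.
#'
#' @param sweeps List of `fscv_transient` objects in delivery order.
#' @param policy Selection policy; only `"middle_three"` is defined.
#' @return A list with `mean_imax`, `mean_tau1`, `n`, `selected` (indices).
#' @export
summarize_fscv_session <- function(sweeps, policy = "middle_three") {
  if (policy != "middle_three")
    abort_striatr("unknown policy", "striatr_invalid_parameter")
  n <- length(sweeps)
  if (n < 3L)
    abort_striatr("need at least 3 accepted sweeps",
                  "striatr_insufficient_sweeps")
  c0 <- ceiling(n / 2)
  sel <- (c0 - 1L):(c0 + 1L)
  imax <- vapply(sweeps[sel], `[[`, numeric(1), "imax")
  tau1 <- vapply(sweeps[sel], `[[`, numeric(1), "tau1")
  list(mean_imax = mean(imax), mean_tau1 = mean(tau1), n = 3L,
       selected = sel)
}
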