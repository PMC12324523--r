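# Dual-channel dFF pipeline: block-mean downsampling, isosbestic
# least-squares correction, dFF = 100*(signal - fitted reference)/fitted
# reference, and full-session z-scoring.

#' Downsample a photometry recording by block averaging
#'
#' Each output sample is the mean of a contiguous non-overlapping block of
#' `factor` input samples (anti-aliasing-safe for the 6 Hz low-passed input,
#' unlike plain decimation); any trailing remainder is dropped. Event
#' timestamps are untouched. The conventional pipeline downsamples the
#' 1017 Hz acquisition by a factor of 10.
#'
#' @param rec A [photometry_recording()].
#' @param factor Integer >= 1.
#' @return A [photometry_recording()] with `fs = rec$fs / factor`.
#' @export
downsample <- function(rec, factor = 10) {
  if (!inherits(rec, "photometry_recording"))
    abort_striatr("rec must be a photometry_recording",
                  "striatr_invalid_parameter")
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor))
    abort_striatr("factor must be an integer >= 1",
                  "striatr_invalid_parameter")
  factor <- as.integer(factor)
  if (factor == 1L) return(rec)
  n_out <- length(rec$time_s) %/% factor
  if (n_out < 1L)
    abort_striatr("recording shorter than one block",
                  "striatr_invalid_parameter")
  idx <- seq_len(n_out * factor)
  block_mean <- function(x) colMeans(matrix(x[idx], nrow = factor))
  photometry_recording(block_mean(rec$time_s), block_mean(rec$sig_465),
                       block_mean(rec$ref_405), fs = rec$fs / factor,
                       events = rec$events)
}

#' Fit the isosbestic reference to the signal channel
#'
#' Ordinary least squares of the 465 nm signal on the 405 nm reference over
#' the full session: `fitted_405(t) = slope * ref_405(t) + intercept`
#' minimizes the residual sum of squares. The fitted reference is the
#' movement/bleaching control used to normalize the signal channel.
#'
#' @param rec A [photometry_recording()].
#' @return A list of class `reference_fit` with `slope`, `intercept`, `rss`.
#' @export
fit_reference <- function(rec) {
  if (!inherits(rec, "photometry_recording"))
    abort_striatr("rec must be a photometry_recording",
                  "striatr_invalid_parameter")
  x <- rec$ref_405
  y <- rec$sig_465
  if (length(x) < 2L)
    abort_striatr("session must have >= 2 samples", "striatr_invalid_parameter")
  if (sd_pop(x) == 0)
    abort_striatr("reference channel is constant; fit is degenerate",
                  "striatr_degenerate_fit")
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  intercept <- my - slope * mx
  rss <- sum((y - slope * x - intercept)^2)
  structure(list(slope = slope, intercept = intercept, rss = rss),
            class = "reference_fit")
}

#' @export
print.reference_fit <- function(x, ...) {
  cat(sprintf("<reference_fit> slope %.6g, intercept %.6g, rss %.6g\n",
              x$slope, x$intercept, x$rss))
  invisible(x)
}

#' Compute the dFF trace from a recording and reference fit
#'
#' `dff(t) = 100 * (sig_465(t) - fitted_405(t)) / fitted_405(t)` with
#' `fitted_405 = slope * ref_405 + intercept`. The fitted reference must be
#' strictly positive everywhere; otherwise the baseline is unusable and an
#' error reports the first offending time.
#'
#' @param rec A [photometry_recording()].
#' @param fit A `reference_fit` (default: fitted from `rec`).
#' @return A [dff_trace()] (not yet z-scored; see [zscore_dff()]).
#' @export
compute_dff <- function(rec, fit = fit_reference(rec)) {
  fitted <- fit$slope * rec$ref_405 + fit$intercept
  bad <- which(fitted <= 0)
  if (length(bad))
    abort_striatr(
      sprintf("fitted reference is non-positive at t = %.4g s; baseline unusable",
              rec$time_s[bad[1]]),
      "striatr_unusable_baseline")
  dff <- 100 * (rec$sig_465 - fitted) / fitted
  dff_trace(rec$time_s, dff,
            session_mean = mean(dff), session_sd = sd_pop(dff),
            fs = rec$fs, events = rec$events)
}

#' z-score a dFF trace over the full session
#'
#' `zdff = (dff - session_mean) / session_sd` with the population SD
#' (divide by n) taken over the whole session including inter-trial
#' intervals, so the z-scored trace has mean 0 and population SD 1. This
#' absorbs between-animal differences in sensor expression and fiber
#' placement.
#'
#' @param trace A [dff_trace()].
#' @return The trace with `zdff` filled in.
#' @export
zscore_dff <- function(trace) {
  if (!inherits(trace, "dff_trace"))
    abort_striatr("trace must be a dff_trace", "striatr_invalid_parameter")
  if (length(trace$dff) < 2L)
    abort_striatr("cannot z-score a single-sample session",
                  "striatr_degenerate_trace")
  m <- mean(trace$dff)
  s <- sd_pop(trace$dff)
  if (s == 0)
    abort_striatr("dFF has zero variance; z-score undefined",
                  "striatr_degenerate_trace")
  trace$session_mean <- m
  trace$session_sd <- s
  trace$zdff <- (trace$dff - m) / s
  trace
}

#' Full photometry preprocessing pipeline
#'
#' Downsample, fit the isosbestic reference, compute dFF and z-score, in
#' that order.
#'
#' @param rec A [photometry_recording()].
#' @param factor Downsampling factor (default 10).
#' @return A z-scored [dff_trace()].
#' @export
#' @examples
#' tr <- photometry_truth(transient_times = 50, transient_amplitudes = 5)
#' rec <- simulate_photometry(tr, duration = 100, fs = 101.7)
#' z <- process_photometry(rec, factor = 1)
process_photometry <- function(rec, factor = 10) {
  ds <- downsample(rec, factor)
  zscore_dff(compute_dff(ds, fit_reference(ds)))
}
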