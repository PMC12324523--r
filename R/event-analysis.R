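# Peri-event analysis of z-scored dFF traces: trial alignment, ITI
# baseline correction, AUC/peak metrics, spontaneous transient detection by
# peak prominence, and amphetamine-session summary metrics.

# Metric windows (seconds after the event) for the standard task events.
metric_window_for <- function(event_type) {
  switch(event_type,
    lever_extension = c(0, 1.5),
    dipper = ,
    dipper_up = ,
    dipper_presentation = c(0, 1.0),
    reward = ,
    reward_delivery = c(0, 3.0),
    NULL)
}

#' Align a z-scored dFF trace to behavioral events
#'
#' Builds a trials x time matrix: one row per event of `event_type`,
#' sampled on a common relative-time grid spanning `window = c(pre, post)`
#' seconds around the event. Events whose window exceeds the recording
#' bounds are dropped and counted in `n_dropped`.
#'
#' @param trace A z-scored [dff_trace()].
#' @param events Event table (`event_type`, `time_s`, `trial_index`);
#'   defaults to the table attached to the trace.
#' @param event_type Event type to align on, e.g. `"lever_extension"`.
#' @param window `c(pre_s, post_s)`, both positive, seconds before/after.
#' @return A list of class `trial_matrix` with elements `aligned`
#'   (trials x time), `rel_time_s`, `alignment_event`, `trial_index`,
#'   `n_dropped`, `baseline_window`, `baseline_per_trial`, `corrected`.
#' @export
align_to_events <- function(trace, events = trace$events, event_type,
                            window = c(5, 5)) {
  if (is.null(trace$zdff))
    abort_striatr("trace must be z-scored first", "striatr_invalid_parameter")
  events <- validate_events(events)
  ev <- events[events$event_type == event_type, , drop = FALSE]
  if (!nrow(ev))
    abort_striatr(sprintf("no events of type '%s'", event_type),
                  "striatr_empty_alignment")
  fs <- trace$fs
  pre_n <- round(window[1] * fs)
  post_n <- round(window[2] * fs)
  rel_time <- (-pre_n:post_n) / fs
  n <- length(trace$time_s)
  t0 <- trace$time_s[1]

  rows <- list(); kept <- integer(); dropped <- 0L
  for (i in seq_len(nrow(ev))) {
    ctr <- round((ev$time_s[i] - t0) * fs) + 1
    lo <- ctr - pre_n; hi <- ctr + post_n
    if (lo < 1 || hi > n) { dropped <- dropped + 1L; next }
    rows[[length(rows) + 1L]] <- trace$zdff[lo:hi]
    kept <- c(kept, i)
  }
  if (!length(rows))
    abort_striatr("no usable events: every window exceeds recording bounds",
                  "striatr_empty_alignment")
  aligned <- do.call(rbind, rows)
  structure(
    list(aligned = aligned, rel_time_s = rel_time,
         alignment_event = event_type,
         trial_index = ev$trial_index[kept], n_dropped = dropped,
         baseline_window = c(-5, -0.5),
         baseline_per_trial = rep(NA_real_, nrow(aligned)),
         corrected = FALSE),
    class = "trial_matrix"
  )
}

#' @export
print.trial_matrix <- function(x, ...) {
  cat(sprintf(
    "<trial_matrix> %d trials x %d samples around '%s' (%d dropped)%s\n",
    nrow(x$aligned), ncol(x$aligned), x$alignment_event, x$n_dropped,
    if (x$corrected) ", baseline-corrected" else ""))
  invisible(x)
}

#' Subtract the per-trial ITI baseline
#'
#' The baseline is the average signal during the inter-trial interval,
#' -5 to -0.5 s before the alignment event; it is subtracted row-wise so
#' every corrected trial has baseline-window mean zero.
#'
#' @param m A `trial_matrix` from [align_to_events()].
#' @param window Baseline window, seconds relative to the event.
#' @return The corrected `trial_matrix`.
#' @export
baseline_correct <- function(m, window = c(-5, -0.5)) {
  if (!inherits(m, "trial_matrix"))
    abort_striatr("m must be a trial_matrix", "striatr_invalid_parameter")
  sel <- m$rel_time_s >= window[1] & m$rel_time_s <= window[2]
  if (!any(sel))
    abort_striatr("baseline window lies outside the aligned range",
                  "striatr_invalid_window")
  base <- rowMeans(m$aligned[, sel, drop = FALSE])
  m$aligned <- m$aligned - base
  m$baseline_per_trial <- base
  m$baseline_window <- window
  m$corrected <- TRUE
  m
}

#' AUC and peak height of a baseline-corrected trial matrix
#'
#' AUC is the trapezoidal integral of the trial-averaged corrected trace
#' over the event-specific metric window (0-1.5 s after lever extension,
#' 0-1 s after dipper presentation, 0-3 s after reward delivery; or an
#' explicit `window` override). Peak height is the maximum change in the
#' averaged signal within the window provided it exceeds one standard
#' deviation above the local (ITI) baseline; otherwise it is reported
#' absent (`NA`). Per-trial AUCs are returned alongside.
#'
#' @param m A baseline-corrected `trial_matrix`.
#' @param event_type Event type used to resolve the metric window; defaults
#'   to the matrix's alignment event.
#' @param window Optional `c(start, end)` override, seconds.
#' @return A list of class `event_metrics`: `auc` (session mean),
#'   `auc_per_trial`, `peak_height`, `peak_time_s`, `metric_window`.
#' @export
event_metrics <- function(m, event_type = m$alignment_event, window = NULL) {
  if (!inherits(m, "trial_matrix") || !m$corrected)
    abort_striatr("m must be a baseline-corrected trial_matrix",
                  "striatr_invalid_parameter")
  window <- window %||% metric_window_for(event_type)
  if (is.null(window))
    abort_striatr(sprintf("no metric window known for '%s'; supply `window`",
                          event_type),
                  "striatr_configuration_error")
  sel <- m$rel_time_s >= window[1] & m$rel_time_s <= window[2]
  if (!any(sel))
    abort_striatr("metric window lies outside the aligned range",
                  "striatr_invalid_window")
  tt <- m$rel_time_s[sel]
  avg <- colMeans(m$aligned)
  auc_per_trial <- apply(m$aligned[, sel, drop = FALSE], 1L,
                         function(y) trapz(tt, y))
  auc <- trapz(tt, avg[sel])

  # local baseline: the corrected ITI window (mean 0 by construction);
  # its SD sets the 1-SD threshold the peak must exceed
  bsel <- m$rel_time_s >= m$baseline_window[1] &
    m$rel_time_s <= m$baseline_window[2]
  base_sd <- stats::sd(avg[bsel])
  pk_i <- which.max(avg[sel])
  pk <- avg[sel][pk_i]
  has_peak <- is.finite(base_sd) && pk > base_sd
  structure(
    list(auc = auc, auc_per_trial = auc_per_trial,
         peak_height = if (has_peak) pk else NA_real_,
         peak_time_s = if (has_peak) tt[pk_i] else NA_real_,
         metric_window = window),
    class = "event_metrics"
  )
}

#' @export
print.event_metrics <- function(x, ...) {
  cat(sprintf(
    "<event_metrics> AUC %.4g zdFF*s over [%g, %g] s; peak %s\n",
    x$auc, x$metric_window[1], x$metric_window[2],
    if (is.na(x$peak_height)) "absent"
    else sprintf("%.4g at %.3g s", x$peak_height, x$peak_time_s)))
  invisible(x)
}

# Local maxima (strictly greater than both neighbors) of a numeric vector,
# with prominences computed by the standard topographic definition: extend
# from the peak in each direction until a strictly higher sample or the
# signal edge, take the minimum over each span, and measure the drop to the
# higher of the two minima.
find_peaks <- function(x) {
  n <- length(x)
  if (n < 3L) return(data.frame(index = integer(), value = numeric(),
                                prominence = numeric()))
  i <- 2:(n - 1)
  peaks <- i[x[i] > x[i - 1] & x[i] > x[i + 1]]
  prom <- vapply(peaks, function(p) {
    higher_left <- which(x[seq_len(p - 1)] > x[p])
    lo <- if (length(higher_left)) max(higher_left) + 1L else 1L
    left_min <- min(x[lo:(p - 1)])
    right <- seq.int(p + 1L, n)
    higher_right <- right[x[right] > x[p]]
    hi <- if (length(higher_right)) min(higher_right) - 1L else n
    right_min <- min(x[(p + 1L):hi])
    x[p] - max(left_min, right_min)
  }, numeric(1))
  data.frame(index = peaks, value = x[peaks], prominence = prom)
}

# Full width at half prominence by linear interpolation around a peak.
peak_width <- function(x, t, p, prom) {
  half <- x[p] - prom / 2
  left <- t[p]
  for (j in seq.int(p - 1L, 1L)) {
    if (x[j] <= half) {
      frac <- (x[j + 1L] - half) / (x[j + 1L] - x[j])
      left <- t[j + 1L] - frac * (t[j + 1L] - t[j])
      break
    }
    left <- t[j]
  }
  right <- t[p]
  n <- length(x)
  for (j in seq.int(p + 1L, n)) {
    if (x[j] <= half) {
      frac <- (x[j - 1L] - half) / (x[j - 1L] - x[j])
      right <- t[j - 1L] + frac * (t[j] - t[j - 1L])
      break
    }
    right <- t[j]
  }
  right - left
}

#' Detect spontaneous dopamine transients during ITIs
#'
#' Local maxima of the z-scored dFF within each inter-trial-interval span
#' are retained when their topographic prominence exceeds
#' `threshold_sd` session standard deviations (default 2). The wording of
#' the original criterion ("prominence exceeding two standard deviations
#' above the session mean") is ambiguous because prominence is a relative
#' quantity; the default reads it as a prominence threshold, and
#' `mode = "height"` provides the alternative reading (peak value above
#' session mean + `threshold_sd` SD). For each retained peak a (-2, +2) s
#' window is extracted and prominence, amplitude and full width at half
#' prominence are reported.
#'
#' @param trace A z-scored [dff_trace()].
#' @param iti_spans List of `c(start_s, end_s)` ITI spans (non-overlapping,
#'   within the recording), or a 2-column matrix.
#' @param threshold_sd Threshold in session SD units (default 2).
#' @param mode `"prominence"` (default) or `"height"`.
#' @return A `data.frame` with one row per detected transient:
#'   `peak_time_s`, `amplitude`, `prominence`, `width_s`, sorted by time.
#' @export
detect_spontaneous <- function(trace, iti_spans, threshold_sd = 2,
                               mode = c("prominence", "height")) {
  mode <- match.arg(mode)
  if (is.null(trace$zdff))
    abort_striatr("trace must be z-scored first", "striatr_invalid_parameter")
  if (is.matrix(iti_spans))
    iti_spans <- lapply(seq_len(nrow(iti_spans)), function(i) iti_spans[i, ])
  empty <- data.frame(peak_time_s = numeric(), amplitude = numeric(),
                      prominence = numeric(), width_s = numeric())
  if (!length(iti_spans)) return(empty)
  starts <- vapply(iti_spans, `[`, numeric(1), 1L)
  ends <- vapply(iti_spans, `[`, numeric(1), 2L)
  ord <- order(starts)
  if (any(starts[ord][-1] < ends[ord][-length(ord)]))
    abort_striatr("iti_spans must be non-overlapping",
                  "striatr_invalid_parameter")

  z <- trace$zdff
  s_sd <- sd_pop(z)
  s_mean <- mean(z)
  out <- list()
  for (sp in iti_spans) {
    sel <- which(trace$time_s >= sp[1] & trace$time_s <= sp[2])
    if (length(sel) < 3L) next
    seg <- z[sel]
    seg_t <- trace$time_s[sel]
    pk <- find_peaks(seg)
    keep <- if (mode == "prominence") pk$prominence > threshold_sd * s_sd
            else pk$value > s_mean + threshold_sd * s_sd
    pk <- pk[keep, , drop = FALSE]
    if (!nrow(pk)) next
    w <- vapply(seq_len(nrow(pk)), function(i)
      peak_width(seg, seg_t, pk$index[i], pk$prominence[i]), numeric(1))
    out[[length(out) + 1L]] <- data.frame(
      peak_time_s = seg_t[pk$index], amplitude = pk$value,
      prominence = pk$prominence, width_s = w)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$peak_time_s), ]
  rownames(res) <- NULL
  res
}

#' Extract the (-2, +2) s window around a detected transient
#'
#' @param trace A z-scored [dff_trace()].
#' @param peak_time_s Peak time, seconds.
#' @param half_window_s Half-width of the extracted window (default 2 s).
#' @return A list with `rel_time_s` and `zdff`.
#' @export
transient_window <- function(trace, peak_time_s, half_window_s = 2) {
  sel <- trace$time_s >= peak_time_s - half_window_s &
    trace$time_s <= peak_time_s + half_window_s
  list(rel_time_s = trace$time_s[sel] - peak_time_s, zdff = trace$zdff[sel])
}

#' Amphetamine-session metrics: mean dFF, slope, latency to plateau
#'
#' `mean_dff` is the mean z-scored dFF over `(injection, injection +
#' horizon]`. The latency to plateau is the first time at which the 60
#' s-moving-average of the signal reaches 95 percent of its post-injection
#' maximum and stays at or above that level for at least 120 s; `slope` is
#' the OLS slope of zdFF against time from the injection to plateau onset
#' (or over the whole horizon when no plateau is reached, flagged via
#' `plateau_reached`).
#'
#' @param trace A z-scored [dff_trace()].
#' @param injection_time_s Injection time, seconds.
#' @param horizon_s Analysis horizon after injection, seconds.
#' @param smooth_s Smoothing window for plateau detection, seconds.
#' @param plateau_frac Fraction of the post-injection maximum defining the
#'   plateau (default 0.95).
#' @param sustain_s Time the smoothed signal must stay above threshold.
#' @param dose Optional dose label (mg/kg), carried through.
#' @return A list of class `amphetamine_metrics`.
#' @export
amphetamine_metrics <- function(trace, injection_time_s, horizon_s,
                                smooth_s = 60, plateau_frac = 0.95,
                                sustain_s = 120, dose = NA_real_) {
  if (is.null(trace$zdff))
    abort_striatr("trace must be z-scored first", "striatr_invalid_parameter")
  t_end <- injection_time_s + horizon_s
  if (injection_time_s < trace$time_s[1] || t_end > max(trace$time_s))
    abort_striatr("injection + horizon must lie within the recording",
                  "striatr_invalid_window")
  fs <- trace$fs
  post <- which(trace$time_s > injection_time_s & trace$time_s <= t_end)
  z_post <- trace$zdff[post]
  t_post <- trace$time_s[post]
  mean_dff <- mean(z_post)

  sm <- moving_average(z_post, round(smooth_s * fs))
  thr <- plateau_frac * max(sm)
  sustain_n <- max(1L, round(sustain_s * fs))
  above <- sm >= thr
  lat <- NA_real_
  plat_idx <- NA_integer_
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= sustain_n)
  if (length(ok)) {
    plat_idx <- starts[ok[1]]
    lat <- t_post[plat_idx] - injection_time_s
  }

  rise <- if (is.na(plat_idx)) seq_along(t_post) else seq_len(plat_idx)
  slope <- if (length(rise) >= 2 && sd_pop(t_post[rise]) > 0)
    stats::cov(t_post[rise], z_post[rise]) / stats::var(t_post[rise])
  else NA_real_

  structure(
    list(mean_dff = mean_dff, slope = slope, latency_to_plateau_s = lat,
         plateau_reached = !is.na(lat), dose = dose,
         injection_time_s = injection_time_s, horizon_s = horizon_s),
    class = "amphetamine_metrics"
  )
}

#' @export
print.amphetamine_metrics <- function(x, ...) {
  cat(sprintf(
    "<amphetamine_metrics> mean dFF %.4g, slope %.4g /s, latency %s\n",
    x$mean_dff, x$slope,
    if (x$plateau_reached) sprintf("%.4g s", x$latency_to_plateau_s)
    else "undefined (no plateau)"))
  invisible(x)
}

#' Correlate a dopamine metric with behavioral latency
#'
#' Pearson correlation of per-trial AUC against per-trial press latency;
#' pairs with a missing latency are dropped. Used to probe whether greater
#' dopamine release predicts faster responding.
#'
#' @param per_trial_auc Numeric vector.
#' @param per_trial_latency Numeric vector of equal length (NA allowed).
#' @return A list with `r`, `n` and `flag` (`"ok"` or `"zero_variance"`).
#' @export
correlate_metric_latency <- function(per_trial_auc, per_trial_latency) {
  if (length(per_trial_auc) != length(per_trial_latency))
    abort_striatr("inputs must have equal length", "striatr_invalid_parameter")
  keep <- is.finite(per_trial_auc) & is.finite(per_trial_latency)
  x <- per_trial_auc[keep]; y <- per_trial_latency[keep]
  if (length(x) < 3L)
    abort_striatr("need at least 3 complete pairs",
                  "striatr_insufficient_data")
  if (sd_pop(x) == 0 || sd_pop(y) == 0)
    return(list(r = NA_real_, n = length(x), flag = "zero_variance"))
  list(r = stats::cor(x, y), n = length(x), flag = "ok")
}
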