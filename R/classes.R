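#' Construct a two-channel photometry recording
#'
#' Container for a raw fiber-photometry session: the 465 nm dopamine-sensor
#' channel, the 405 nm isosbestic reference channel (dopamine-independent,
#' capturing motion and photobleaching), a uniform time base, and an optional
#' table of behavioral events.
#'
#' @param time_s Numeric vector of sample times in seconds, strictly
#'   increasing on a uniform grid.
#' @param sig_465 Fluorescence of the 465 nm (signal) channel, arbitrary units.
#' @param ref_405 Fluorescence of the 405 nm (reference) channel, arbitrary
#'   units.
#' @param fs Sampling rate in Hz. Defaults to the reciprocal median time step.
#' @param events Optional `data.frame` with columns `event_type`, `time_s`,
#'   `trial_index`.
#' @return An object of class `photometry_recording`.
#' @export
photometry_recording <- function(time_s, sig_465, ref_405, fs = NULL,
                                 events = NULL) {
  if (length(time_s) != length(sig_465) || length(time_s) != length(ref_405))
    abort_striatr("channels and time base must have equal length",
                  "striatr_invalid_parameter")
  if (!is_uniform_grid(time_s))
    abort_striatr("time_s must be strictly increasing on a uniform grid",
                  "striatr_invalid_parameter")
  if (is.null(fs)) fs <- 1 / stats::median(diff(time_s))
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  if (!is.null(events)) events <- validate_events(events)
  structure(
    list(time_s = as.numeric(time_s), sig_465 = as.numeric(sig_465),
         ref_405 = as.numeric(ref_405), fs = fs, events = events),
    class = "photometry_recording"
  )
}

validate_events <- function(events) {
  req <- c("event_type", "time_s")
  if (!is.data.frame(events) || !all(req %in% names(events)))
    abort_striatr("events must be a data.frame with event_type and time_s",
                  "striatr_invalid_parameter")
  if (is.null(events$trial_index)) events$trial_index <- NA_integer_
  events
}

#' @export
print.photometry_recording <- function(x, ...) {
  cat(sprintf(
    "<photometry_recording> %d samples @ %.6g Hz (%.1f s), %d events\n",
    length(x$time_s), x$fs, diff(range(x$time_s)),
    if (is.null(x$events)) 0L else nrow(x$events)))
  invisible(x)
}

#' Construct a dFF trace
#'
#' Holds the isosbestic-corrected fractional fluorescence change
#' (`dff`, percent) and its session z-score (`zdff`), together with the
#' session mean and population standard deviation used for z-scoring.
#'
#' @param time_s Sample times, seconds.
#' @param dff dFF in percent.
#' @param zdff z-scored dFF (may be `NULL` until [zscore_dff()] is applied).
#' @param session_mean,session_sd Session mean and population SD of `dff`.
#' @param fs Sampling rate, Hz.
#' @param events Optional event table carried over from the recording.
#' @return An object of class `dff_trace`.
#' @export
dff_trace <- function(time_s, dff, zdff = NULL, session_mean = NA_real_,
                      session_sd = NA_real_, fs = NULL, events = NULL) {
  if (length(time_s) != length(dff))
    abort_striatr("time_s and dff must have equal length",
                  "striatr_invalid_parameter")
  if (is.null(fs)) fs <- 1 / stats::median(diff(time_s))
  structure(
    list(time_s = as.numeric(time_s), dff = as.numeric(dff),
         zdff = if (is.null(zdff)) NULL else as.numeric(zdff),
         session_mean = session_mean, session_sd = session_sd,
         fs = fs, events = events),
    class = "dff_trace"
  )
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf(
    "<dff_trace> %d samples @ %.6g Hz; session mean %.4g%%, sd %.4g%%%s\n",
    length(x$time_s), x$fs, x$session_mean, x$session_sd,
    if (is.null(x$zdff)) " (not z-scored)" else " (z-scored)"))
  invisible(x)
}

#' Construct an FSCV trace
#'
#' A single evoked-transient time course extracted from fast-scan cyclic
#' voltammetry (one value per voltammogram), in electrode current (pA) or
#' dopamine concentration (uM) after calibration against a 1 uM standard.
#'
#' @param time_s Sample times, seconds; uniform grid.
#' @param value Current (pA) or concentration (uM).
#' @param units `"pA"` or `"uM"`.
#' @param stim_time_s Stimulation time, seconds; must lie inside the trace.
#' @param calibration_factor uM per pA, from the 1 uM dopamine standard.
#' @return An object of class `fscv_trace`.
#' @export
fscv_trace <- function(time_s, value, units = c("pA", "uM"),
                       stim_time_s, calibration_factor = NA_real_) {
  units <- match.arg(units)
  if (length(time_s) != length(value))
    abort_striatr("time_s and value must have equal length",
                  "striatr_invalid_parameter")
  if (!is_uniform_grid(time_s))
    abort_striatr("FSCV trace requires uniform sampling",
                  "striatr_invalid_parameter")
  stopifnot_scalar_number(stim_time_s, "stim_time_s")
  if (stim_time_s < min(time_s) || stim_time_s > max(time_s))
    abort_striatr("stim_time_s must lie within the trace",
                  "striatr_invalid_parameter")
  structure(
    list(time_s = as.numeric(time_s), value = as.numeric(value),
         units = units, stim_time_s = stim_time_s,
         calibration_factor = calibration_factor),
    class = "fscv_trace"
  )
}

#' @export
print.fscv_trace <- function(x, ...) {
  cat(sprintf("<fscv_trace> %d samples, units %s, stim at %.3g s\n",
              length(x$time_s), x$units, x$stim_time_s))
  invisible(x)
}

#' Construct an epoch-binned activity series
#'
#' Piezo-derived activity per fixed epoch (normalized movement intensity,
#' clipped to \[0, 0.3\]) with a binary sleep/wake state per epoch and a
#' 12:12 light/dark schedule. The recording is assumed to start at lights-on
#' (zeitgeber time ZT0) unless `start_zt_h` says otherwise.
#'
#' @param epoch_start_s Epoch start times, seconds since recording start.
#' @param activity Normalized activity per epoch, in \[0, 0.3\].
#' @param sleep_state Binary vector, 1 = asleep.
#' @param epoch_s Epoch length, seconds.
#' @param light_on Clock hour of lights-on (default 6, i.e. 06:00).
#' @param start_zt_h Zeitgeber hour at the first epoch (default 0).
#' @return An object of class `activity_series`.
#' @export
activity_series <- function(epoch_start_s, activity, sleep_state = NULL,
                            epoch_s = NULL, light_on = 6, start_zt_h = 0) {
  if (length(epoch_start_s) != length(activity))
    abort_striatr("epoch_start_s and activity must have equal length",
                  "striatr_invalid_parameter")
  if (is.null(epoch_s)) epoch_s <- stats::median(diff(epoch_start_s))
  if (!is_uniform_grid(epoch_start_s))
    abort_striatr("epochs must be uniform", "striatr_invalid_parameter")
  if (any(activity < -1e-9 | activity > 0.3 + 1e-9))
    abort_striatr("activity must lie within [0, 0.3]",
                  "striatr_invalid_parameter")
  if (is.null(sleep_state)) sleep_state <- rep(NA_integer_, length(activity))
  n_days <- length(activity) * epoch_s / 86400
  structure(
    list(epoch_start_s = as.numeric(epoch_start_s),
         activity = as.numeric(activity),
         sleep_state = as.integer(sleep_state),
         epoch_s = epoch_s, light_on = light_on, start_zt_h = start_zt_h,
         n_days = n_days),
    class = "activity_series"
  )
}

#' @export
print.activity_series <- function(x, ...) {
  cat(sprintf(
    "<activity_series> %d epochs of %.0f s (%.2f days), lights-on %02d:00\n",
    length(x$activity), x$epoch_s, x$n_days, x$light_on))
  invisible(x)
}

#' Construct an operant session
#'
#' A normalized, causally ordered event log for trough (dipper) training,
#' continuous-reinforcement (CRF) or fixed-interval (FI) schedules. Event
#' vocabulary: `lever_extension`, `lever_press`, `dipper_up`, `dipper_down`,
#' `head_entry`.
#'
#' @param events `data.frame` with columns `event_type`, `time_s`,
#'   `trial_index`, sorted by time.
#' @param schedule One of `"trough"`, `"CRF"`, `"FI"`.
#' @param fixed_interval_s Fixed interval in seconds (FI only).
#' @param session_end_s Session end time, seconds.
#' @return An object of class `operant_session`.
#' @export
operant_session <- function(events, schedule = c("CRF", "FI", "trough"),
                            fixed_interval_s = NA_real_,
                            session_end_s = NA_real_) {
  schedule <- match.arg(schedule)
  events <- validate_events(events)
  if (is.unsorted(events$time_s))
    abort_striatr("event times must be nondecreasing",
                  "striatr_invalid_parameter")
  if (schedule == "FI" && !is.finite(fixed_interval_s))
    abort_striatr("FI schedule requires fixed_interval_s",
                  "striatr_invalid_parameter")
  validate_causal_order(events)
  if (!is.finite(session_end_s)) session_end_s <- max(events$time_s)
  structure(
    list(events = events, schedule = schedule,
         fixed_interval_s = fixed_interval_s, session_end_s = session_end_s),
    class = "operant_session"
  )
}

# Per trial: lever_extension precedes every press; the press that triggers
# the dipper precedes dipper_up. Presses while the lever is retracted are a
# malformed log and rejected.
validate_causal_order <- function(events) {
  for (tr in unique(stats::na.omit(events$trial_index))) {
    ev <- events[!is.na(events$trial_index) & events$trial_index == tr, ]
    ext <- ev$time_s[ev$event_type == "lever_extension"]
    press <- ev$time_s[ev$event_type == "lever_press"]
    dip <- ev$time_s[ev$event_type == "dipper_up"]
    if (length(press) && length(ext) && min(press) < min(ext))
      abort_striatr(sprintf("trial %s: press before lever extension", tr),
                    "striatr_invalid_parameter")
    if (length(dip) && length(press) && min(dip) < min(press) &&
        length(ext))
      abort_striatr(sprintf("trial %s: dipper before any press", tr),
                    "striatr_invalid_parameter")
  }
  invisible(events)
}

#' @export
print.operant_session <- function(x, ...) {
  cat(sprintf("<operant_session> %s schedule, %d events, %d trials%s\n",
              x$schedule, nrow(x$events),
              length(unique(stats::na.omit(x$events$trial_index))),
              if (is.finite(x$fixed_interval_s))
                sprintf(", FI %g s", x$fixed_interval_s) else ""))
  invisible(x)
}

#' Construct a gustometer lick log
#'
#' @param trials `data.frame` with columns `trial_index`, `concentration`
#'   (percent evaporated milk), `onset_s`.
#' @param licks `data.frame` with columns `trial_index`, `time_s` (one row
#'   per lick).
#' @return An object of class `lick_log`.
#' @export
lick_log <- function(trials, licks) {
  if (!is.data.frame(trials) ||
      !all(c("trial_index", "concentration", "onset_s") %in% names(trials)))
    abort_striatr("trials needs trial_index, concentration, onset_s",
                  "striatr_invalid_parameter")
  if (!is.data.frame(licks) ||
      !all(c("trial_index", "time_s") %in% names(licks)))
    abort_striatr("licks needs trial_index, time_s",
                  "striatr_invalid_parameter")
  structure(list(trials = trials, licks = licks), class = "lick_log")
}

#' @export
print.lick_log <- function(x, ...) {
  cat(sprintf("<lick_log> %d trials, %d licks, %d concentrations\n",
              nrow(x$trials), nrow(x$licks),
              length(unique(x$trials$concentration))))
  invisible(x)
}

#' Extract generator ground truth
#'
#' Every synthetic generator stores its ground-truth parameters on the
#' returned object; this accessor retrieves them for test harnesses.
#'
#' @param x An object produced by a `simulate_*` generator.
#' @return A list of ground-truth parameters, or `NULL`.
#' @export
ground_truth <- function(x) attr(x, "ground_truth", exact = TRUE)
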