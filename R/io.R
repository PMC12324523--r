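# Delimited-text readers/writers for the package's data contracts.
# Photometry streams: CSV with columns time_s, sig_465, ref_405.
# Events: CSV with columns event_type, time_s, trial_index.
# FSCV: CSV time_s, value plus a JSON sidecar (units, stim_time,
#   calibration factor). Activity: CSV epoch_start_s, activity, sleep_state
#   plus a JSON sidecar holding the light schedule. Ground truth from any
#   generator can be written as a JSON sidecar for test harnesses.

#' Write / read a photometry recording as CSV
#'
#' @param rec A [photometry_recording()].
#' @param path Output CSV path (`time_s, sig_465, ref_405`).
#' @param events_path Optional events CSV path.
#' @return `path`, invisibly (writer); a [photometry_recording()] (reader).
#' @export
write_photometry <- function(rec, path, events_path = NULL) {
  utils::write.csv(
    data.frame(time_s = rec$time_s, sig_465 = rec$sig_465,
               ref_405 = rec$ref_405),
    path, row.names = FALSE)
  if (!is.null(events_path) && !is.null(rec$events))
    write_events(rec$events, events_path)
  invisible(path)
}

#' @rdname write_photometry
#' @param path Path of a CSV written by [write_photometry()].
#' @export
read_photometry <- function(path, events_path = NULL) {
  d <- utils::read.csv(path)
  events <- if (!is.null(events_path)) read_events(events_path) else NULL
  photometry_recording(d$time_s, d$sig_465, d$ref_405, events = events)
}

#' Write / read an event table as CSV
#'
#' @param events `data.frame` with `event_type`, `time_s`, `trial_index`.
#' @param path CSV path.
#' @export
write_events <- function(events, path) {
  utils::write.csv(validate_events(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) validate_events(utils::read.csv(path))

#' Write / read an FSCV trace as CSV plus JSON sidecar
#'
#' @param trace An [fscv_trace()].
#' @param path CSV path; metadata goes to `<path>.json`.
#' @export
write_fscv <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$time_s, value = trace$value),
                   path, row.names = FALSE)
  jsonlite::write_json(
    list(units = trace$units, stim_time_s = trace$stim_time_s,
         calibration_factor = trace$calibration_factor),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fscv
#' @export
read_fscv <- function(path) {
  d <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  fscv_trace(d$time_s, d$value, units = meta$units,
             stim_time_s = meta$stim_time_s,
             calibration_factor = meta$calibration_factor %||% NA_real_)
}

#' Write / read an activity series as CSV plus JSON sidecar
#'
#' @param s An [activity_series()].
#' @param path CSV path (`epoch_start_s, activity, sleep_state`); the light
#'   schedule goes to `<path>.json`.
#' @export
write_activity <- function(s, path) {
  utils::write.csv(
    data.frame(epoch_start_s = s$epoch_start_s, activity = s$activity,
               sleep_state = s$sleep_state),
    path, row.names = FALSE)
  jsonlite::write_json(
    list(epoch_s = s$epoch_s, light_on = s$light_on,
         start_zt_h = s$start_zt_h),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_activity
#' @export
read_activity <- function(path) {
  d <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  activity_series(d$epoch_start_s, d$activity, sleep_state = d$sleep_state,
                  epoch_s = meta$epoch_s, light_on = meta$light_on,
                  start_zt_h = meta$start_zt_h)
}

#' Write / read an operant session as CSV plus JSON sidecar
#'
#' @param s An [operant_session()].
#' @param path CSV events path; schedule metadata goes to `<path>.json`.
#' @export
write_operant <- function(s, path) {
  utils::write.csv(s$events, path, row.names = FALSE)
  jsonlite::write_json(
    list(schedule = s$schedule, fixed_interval_s = s$fixed_interval_s,
         session_end_s = s$session_end_s),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_operant
#' @export
read_operant <- function(path) {
  ev <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  operant_session(ev, schedule = meta$schedule,
                  fixed_interval_s = meta$fixed_interval_s %||% NA_real_,
                  session_end_s = meta$session_end_s %||% NA_real_)
}

#' Write generator ground truth as a JSON sidecar
#'
#' @param x An object from a `simulate_*` generator.
#' @param path JSON output path.
#' @export
write_ground_truth <- function(x, path) {
  gt <- ground_truth(x)
  if (is.null(gt))
    abort_striatr("object carries no ground truth", "striatr_invalid_parameter")
  gt <- gt[!vapply(gt, is.function, logical(1))]
  gt <- lapply(gt, function(el)
    if (inherits(el, "schedule_spec"))
      unclass(el)[!vapply(el, is.function, logical(1))] else el)
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write a dFF trace as CSV
#'
#' @param trace A [dff_trace()].
#' @param path CSV path (`time_s, dff, zdff`).
#' @export
write_dff <- function(trace, path) {
  utils::write.csv(
    data.frame(time_s = trace$time_s, dff = trace$dff,
               zdff = if (is.null(trace$zdff)) NA_real_ else trace$zdff),
    path, row.names = FALSE)
  invisible(path)
}
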