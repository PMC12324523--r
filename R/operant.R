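# Behavioral metrics from normalized operant and gustometer event logs.
#
# Conventions: a trial is "answered" when it has >= 1 lever press; a reward
# is "consumed" when >= 1 head entry falls inside the dipper-up period;
# missing latencies (no press, no retrieval) are excluded from means, never
# imputed, and the number of such trials is reported.

trial_split <- function(s) {
  ev <- s$events
  split(ev, ev$trial_index)
}

per_trial_metrics <- function(s) {
  trials <- trial_split(s)
  out <- lapply(trials, function(ev) {
    ext <- ev$time_s[ev$event_type == "lever_extension"]
    press <- ev$time_s[ev$event_type == "lever_press"]
    dip_up <- ev$time_s[ev$event_type == "dipper_up"]
    dip_dn <- ev$time_s[ev$event_type == "dipper_down"]
    he <- ev$time_s[ev$event_type == "head_entry"]
    presented <- length(ext) > 0
    pressed <- presented && length(press) > 0
    first_press <- if (pressed) min(press) - min(ext) else NA_real_
    mean_press <- if (pressed) mean(press - min(ext)) else NA_real_
    consumed <- FALSE
    lat_reward <- NA_real_
    if (length(dip_up)) {
      up <- min(dip_up)
      dn <- if (length(dip_dn)) min(dip_dn[dip_dn >= up]) else Inf
      he_in <- he[he >= up & he <= dn]
      consumed <- length(he_in) > 0
      if (consumed) lat_reward <- min(he_in) - up
    }
    data.frame(trial_index = ev$trial_index[1], presented = presented,
               pressed = pressed, n_presses = length(press),
               rewarded = length(dip_up) > 0, consumed = consumed,
               latency_first_press_s = first_press,
               latency_mean_press_s = mean_press,
               latency_reward_s = lat_reward)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

behavioral_metrics <- function(tab, mean_press_over = "all") {
  n_pres <- sum(tab$presented)
  mean_press <- if (mean_press_over == "all") {
    # weight every press equally across the session
    w <- tab$n_presses[tab$pressed]
    stats::weighted.mean(tab$latency_mean_press_s[tab$pressed], w)
  } else {
    mean(tab$latency_first_press_s[tab$pressed])
  }
  structure(
    list(
      pct_lever_press = 100 * sum(tab$pressed) / n_pres,
      pct_rewarded_trials = 100 * sum(tab$pressed & tab$consumed) / n_pres,
      latency_first_press_s = mean(tab$latency_first_press_s, na.rm = TRUE),
      latency_mean_press_s = mean_press,
      latency_reward_s = mean(tab$latency_reward_s, na.rm = TRUE),
      total_presses = sum(tab$n_presses),
      n_presented = n_pres,
      n_missing_press = sum(tab$presented & !tab$pressed),
      n_missing_reward = sum(tab$rewarded & !tab$consumed),
      per_trial = tab),
    class = "behavioral_metrics"
  )
}

#' @export
print.behavioral_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("<behavioral_metrics> %d trials: %.1f%% pressed, %.1f%% rewarded,",
           " %d presses\n  latency first press %.3g s, mean press %.3g s,",
           " reward %.3g s\n"),
    x$n_presented, x$pct_lever_press, x$pct_rewarded_trials, x$total_presses,
    x$latency_first_press_s, x$latency_mean_press_s, x$latency_reward_s))
  invisible(x)
}

#' Continuous-reinforcement (CRF) session metrics
#'
#' Percent of lever presentations answered with at least one press, percent
#' of presentations with both a press and reward consumption (head entry
#' during dipper-up), per-trial press and reward-retrieval latencies, and
#' total presses.
#'
#' @param s An [operant_session()] with `schedule == "CRF"`.
#' @param mean_press_over `"all"` (default: average over all presses) or
#'   `"first"` (average over per-trial first presses).
#' @return A `behavioral_metrics` list (per-trial table in `$per_trial`).
#' @export
crf_metrics <- function(s, mean_press_over = c("all", "first")) {
  mean_press_over <- match.arg(mean_press_over)
  if (!inherits(s, "operant_session") || s$schedule != "CRF")
    abort_striatr("expected a CRF operant_session",
                  "striatr_schedule_mismatch")
  behavioral_metrics(per_trial_metrics(s), mean_press_over)
}

#' Fixed-interval (FI) session metrics
#'
#' As [crf_metrics()], with presses during the whole lever-extension period
#' counted in `total_presses`; under FI only the first press after the
#' fixed interval elapses triggers the reward.
#'
#' @param s An [operant_session()] with `schedule == "FI"`.
#' @inheritParams crf_metrics
#' @return A `behavioral_metrics` list.
#' @export
fi_metrics <- function(s, mean_press_over = c("all", "first")) {
  mean_press_over <- match.arg(mean_press_over)
  if (!inherits(s, "operant_session") || s$schedule != "FI")
    abort_striatr("expected an FI operant_session",
                  "striatr_schedule_mismatch")
  behavioral_metrics(per_trial_metrics(s), mean_press_over)
}

#' Within-interval press-rate ("scallop") curve
#'
#' Pools presses falling within `[extension, extension + interval)` across
#' trials, bins them into `n_bins` equal slices of the interval and reports
#' the press rate per bin (presses / (trials * bin duration)). Under a
#' fixed-interval schedule the rate climbs toward the end of the interval —
#' the classic scalloping signature of interval timing.
#'
#' @param s An [operant_session()] with `schedule == "FI"`.
#' @param n_bins Number of bins (>= 2 unless a single-bin overall rate is
#'   wanted).
#' @param normalize If `TRUE`, divide by the final bin's rate.
#' @return A `data.frame` with `bin_start_s`, `bin_end_s`, `rate_hz`
#'   (or normalized rate) and an attribute `flag = "no_presses"` when the
#'   session has no in-interval presses.
#' @export
scallop_curve <- function(s, n_bins = 10, normalize = FALSE) {
  if (!inherits(s, "operant_session") || s$schedule != "FI")
    abort_striatr("expected an FI operant_session",
                  "striatr_schedule_mismatch")
  if (n_bins < 1)
    abort_striatr("n_bins must be >= 1", "striatr_invalid_parameter")
  fi <- s$fixed_interval_s
  trials <- trial_split(s)
  rel <- unlist(lapply(trials, function(ev) {
    ext <- ev$time_s[ev$event_type == "lever_extension"]
    if (!length(ext)) return(numeric())
    press <- ev$time_s[ev$event_type == "lever_press"] - min(ext)
    press[press >= 0 & press < fi]
  }), use.names = FALSE)
  n_trials <- sum(vapply(trials, function(ev)
    any(ev$event_type == "lever_extension"), logical(1)))
  edges <- seq(0, fi, length.out = n_bins + 1)
  counts <- if (length(rel))
    tabulate(findInterval(rel, edges, rightmost.closed = FALSE,
                          all.inside = TRUE), nbins = n_bins)
  else rep(0L, n_bins)
  rate <- counts / (n_trials * fi / n_bins)
  out <- data.frame(bin_start_s = edges[-(n_bins + 1)],
                    bin_end_s = edges[-1], n_presses = counts,
                    rate_hz = rate)
  if (normalize) {
    last <- rate[n_bins]
    out$rate_norm <- if (last > 0) rate / last else rep(NA_real_, n_bins)
  }
  if (!length(rel)) attr(out, "flag") <- "no_presses"
  out
}

#' Gustometer lick-session metrics
#'
#' Trials presented, completed (at least one lick) and incomplete; total
#' licks; mean first-lick latency over completed trials; and mean licks per
#' concentration restricted to completed trials (a concentration with no
#' completed trial is reported `NA`, distinguishing absent from zero).
#'
#' @param log A [lick_log()].
#' @return A list of class `lick_metrics`.
#' @export
lick_metrics <- function(log) {
  if (!inherits(log, "lick_log"))
    abort_striatr("log must be a lick_log", "striatr_invalid_parameter")
  trials <- log$trials
  licks <- log$licks
  n_by_trial <- vapply(trials$trial_index, function(i)
    sum(licks$trial_index == i), integer(1))
  completed <- n_by_trial >= 1L
  first_lat <- vapply(seq_len(nrow(trials)), function(i) {
    lt <- licks$time_s[licks$trial_index == trials$trial_index[i]]
    if (!length(lt)) NA_real_ else min(lt) - trials$onset_s[i]
  }, numeric(1))
  concs <- sort(unique(trials$concentration))
  by_conc <- vapply(concs, function(cc) {
    sel <- trials$concentration == cc & completed
    if (!any(sel)) NA_real_ else mean(n_by_trial[sel])
  }, numeric(1))
  names(by_conc) <- concs
  structure(
    list(n_trials_presented = nrow(trials),
         n_completed = sum(completed),
         n_incomplete = sum(!completed),
         total_licks = sum(n_by_trial),
         latency_first_lick_s = if (any(completed))
           mean(first_lat[completed]) else NA_real_,
         latency_defined = any(completed),
         licks_by_concentration = by_conc,
         per_trial = data.frame(trial_index = trials$trial_index,
                                concentration = trials$concentration,
                                n_licks = n_by_trial,
                                completed = completed,
                                latency_first_lick_s = first_lat)),
    class = "lick_metrics"
  )
}

#' @export
print.lick_metrics <- function(x, ...) {
  cat(sprintf(
    "<lick_metrics> %d trials (%d completed), %d licks, first-lick %s\n",
    x$n_trials_presented, x$n_completed, x$total_licks,
    if (x$latency_defined) sprintf("%.3g s", x$latency_first_lick_s)
    else "undefined"))
  invisible(x)
}

#' Trough (dipper) training retrieval percentage
#'
#' Percent of free dipper presentations answered with at least one head
#' entry while the dipper was up (10 s by protocol).
#'
#' @param s An [operant_session()] with `schedule == "trough"`.
#' @return A list with `pct_retrieved`, `n_presented`, `n_retrieved`.
#' @export
trough_training_metrics <- function(s) {
  if (!inherits(s, "operant_session") || s$schedule != "trough")
    abort_striatr("expected a trough operant_session",
                  "striatr_schedule_mismatch")
  trials <- trial_split(s)
  retrieved <- vapply(trials, function(ev) {
    up <- ev$time_s[ev$event_type == "dipper_up"]
    if (!length(up)) return(NA)
    dn <- ev$time_s[ev$event_type == "dipper_down"]
    dn <- if (length(dn)) min(dn[dn >= min(up)]) else min(up) + 10
    any(ev$event_type == "head_entry" &
          ev$time_s >= min(up) & ev$time_s <= dn)
  }, logical(1))
  retrieved <- retrieved[!is.na(retrieved)]
  list(pct_retrieved = 100 * mean(retrieved),
       n_presented = length(retrieved),
       n_retrieved = sum(retrieved))
}
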