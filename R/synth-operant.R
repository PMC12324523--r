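# Synthetic operant and gustometer sessions with known ground truth.

#' Schedule specification for synthetic operant sessions
#'
#' @param schedule `"trough"` (free dipper presentations), `"CRF"`
#'   (continuous reinforcement, every press rewarded) or `"FI"` (fixed
#'   interval; only the first press after the interval elapses is rewarded).
#' @param fixed_interval Fixed interval in seconds; required for FI, and the
#'   tested values are 2, 4, 8, 12 and 24 s.
#' @param n_trials Number of trials (>= 1, at most 60 reinforcements per
#'   session as in standard CRF/FI protocols).
#' @param iti_mean Mean inter-trial interval, seconds (variable ITI,
#'   uniform on 0.5-1.5x the mean). Defaults: 20 s for CRF, 12 s for FI,
#'   30 s for trough.
#' @param reward_duration Dipper-up duration, seconds (5 s CRF, 10 s FI and
#'   trough by default).
#' @param press_rate_profile Function of normalized time-within-interval
#'   `u` in \[0, 1\] returning a press rate in Hz; drives FI "scalloping".
#'   Default rises linearly from 0 to 1 Hz.
#' @return A list of class `schedule_spec`.
#' @export
schedule_spec <- function(schedule = c("CRF", "FI", "trough"),
                          fixed_interval = NULL, n_trials = 30,
                          iti_mean = NULL, reward_duration = NULL,
                          press_rate_profile = function(u) u) {
  schedule <- match.arg(schedule)
  if (n_trials < 1 || n_trials > 60)
    abort_striatr("n_trials must be in [1, 60]", "striatr_invalid_parameter")
  if (schedule == "FI") {
    if (is.null(fixed_interval))
      abort_striatr("FI schedule requires fixed_interval",
                    "striatr_invalid_parameter")
    stopifnot_scalar_number(fixed_interval, "fixed_interval", positive = TRUE)
  }
  iti_mean <- iti_mean %||%
    switch(schedule, CRF = 20, FI = 12, trough = 30)
  reward_duration <- reward_duration %||%
    switch(schedule, CRF = 5, FI = 10, trough = 10)
  structure(
    list(schedule = schedule, fixed_interval = fixed_interval,
         n_trials = as.integer(n_trials), iti_mean = iti_mean,
         reward_duration = reward_duration,
         press_rate_profile = press_rate_profile),
    class = "schedule_spec"
  )
}

draw_latency <- function(model, n = 1L) {
  switch(model$type %||% "exponential",
    deterministic = rep(model$value, n),
    exponential = stats::rexp(n, 1 / model$mean),
    abort_striatr("unknown latency model type", "striatr_invalid_parameter"))
}

# Inhomogeneous Poisson press times on [0, interval) via thinning against
# the profile's maximum rate.
draw_press_times <- function(profile, interval, rate_scale = 1) {
  u_grid <- seq(0, 1, length.out = 201)
  rmax <- max(profile(u_grid)) * rate_scale
  if (rmax <= 0) return(numeric())
  n_cand <- stats::rpois(1, rmax * interval)
  cand <- sort(stats::runif(n_cand, 0, interval))
  keep <- stats::runif(n_cand) < profile(cand / interval) * rate_scale / rmax
  cand[keep]
}

#' Simulate an operant session event log
#'
#' Emits a causally ordered event log for a trough, CRF or FI session. Per
#' trial the order is lever_extension < presses < dipper_up <= head_entry,
#' and under FI only the first press after the fixed interval elapses
#' triggers the dipper. Presses while the lever is retracted never occur by
#' construction.
#'
#' @param spec A [schedule_spec()].
#' @param latency_model List describing the latency from lever extension (or
#'   interval end, under FI) to the operative press:
#'   `list(type = "deterministic", value = s)` or
#'   `list(type = "exponential", mean = s)`.
#' @param retrieve_latency_model Latency from dipper-up to head entry, same
#'   format.
#' @param p_engage Probability a trial is answered at all (press for
#'   CRF/FI, head entry for trough).
#' @param rate_scale Multiplier on the FI press-rate profile.
#' @param seed Integer seed; fixed seed reproduces the log exactly.
#' @return An [operant_session()] carrying ground truth.
#' @export
#' @examples
#' s <- simulate_event_schedule(schedule_spec("CRF", n_trials = 3),
#'   latency_model = list(type = "deterministic", value = 2))
simulate_event_schedule <- function(spec,
                                    latency_model = list(type = "exponential",
                                                         mean = 5),
                                    retrieve_latency_model =
                                      list(type = "exponential", mean = 1),
                                    p_engage = 1, rate_scale = 1,
                                    seed = 1L) {
  if (!inherits(spec, "schedule_spec"))
    abort_striatr("spec must come from schedule_spec()",
                  "striatr_invalid_parameter")
  if (p_engage < 0 || p_engage > 1)
    abort_striatr("p_engage must be in [0, 1]", "striatr_invalid_parameter")

  rows <- list()
  add <- function(type, time, trial)
    rows[[length(rows) + 1L]] <<- data.frame(
      event_type = type, time_s = time, trial_index = trial)

  with_seed(seed, {
    t_now <- 0
    for (tr in seq_len(spec$n_trials)) {
      engaged <- stats::runif(1) < p_engage
      if (spec$schedule == "trough") {
        add("dipper_up", t_now, tr)
        if (engaged)
          add("head_entry", t_now + draw_latency(retrieve_latency_model), tr)
        add("dipper_down", t_now + spec$reward_duration, tr)
        t_now <- t_now + spec$reward_duration +
          stats::runif(1, 0.5, 1.5) * spec$iti_mean
      } else {
        add("lever_extension", t_now, tr)
        reward_t <- NA_real_
        if (spec$schedule == "CRF") {
          if (engaged) {
            press_t <- t_now + draw_latency(latency_model)
            add("lever_press", press_t, tr)
            reward_t <- press_t
          }
        } else {  # FI
          fi <- spec$fixed_interval
          in_int <- draw_press_times(spec$press_rate_profile, fi, rate_scale)
          for (pt in in_int) add("lever_press", t_now + pt, tr)
          if (engaged) {
            press_t <- t_now + fi + draw_latency(latency_model)
            add("lever_press", press_t, tr)
            reward_t <- press_t  # first press after the interval elapses
          }
        }
        if (is.finite(reward_t)) {
          add("dipper_up", reward_t, tr)
          add("head_entry", reward_t + draw_latency(retrieve_latency_model), tr)
          add("dipper_down", reward_t + spec$reward_duration, tr)
          t_now <- reward_t + spec$reward_duration +
            stats::runif(1, 0.5, 1.5) * spec$iti_mean
        } else {
          # unanswered trial: lever retracts after a timeout
          t_now <- t_now + (spec$fixed_interval %||% 0) + 60 +
            stats::runif(1, 0.5, 1.5) * spec$iti_mean
        }
      }
    }
  })

  events <- do.call(rbind, rows)
  events <- events[order(events$time_s, events$trial_index), ]
  rownames(events) <- NULL
  sess <- operant_session(events, schedule = spec$schedule,
                          fixed_interval_s = spec$fixed_interval %||% NA_real_,
                          session_end_s = max(events$time_s))
  attr(sess, "ground_truth") <- list(spec = spec,
                                     latency_model = latency_model,
                                     p_engage = p_engage,
                                     rate_scale = rate_scale, seed = seed)
  sess
}

#' Simulate a gustometer lick session
#'
#' A six-bottle style session: concentrations are presented in a balanced
#' pseudorandom order (shuffled blocks, each block containing every
#' concentration once), each trial is engaged with probability `p_engage`,
#' and engaged trials contain at least one lick (a first lick after a short
#' latency followed by Poisson licking at `lick_rate` for the access
#' period).
#'
#' @param n_trials Number of presented trials.
#' @param concentrations Vector of evaporated-milk concentrations, percent
#'   (default 0, 6.25, 12.5, 25, 50, 100).
#' @param lick_rate Licking rate during engaged access, Hz.
#' @param p_engage Probability a presented trial receives any lick.
#' @param access_s Sipper access duration per trial, seconds.
#' @param iti_s Inter-trial interval, seconds (20 s protocol default).
#' @param first_lick_mean Mean latency of the first lick, seconds.
#' @param seed Integer seed.
#' @return A [lick_log()] carrying ground truth.
#' @export
simulate_lick_session <- function(n_trials = 30,
                                  concentrations = c(0, 6.25, 12.5, 25, 50, 100),
                                  lick_rate = 6, p_engage = 0.8,
                                  access_s = 5, iti_s = 20,
                                  first_lick_mean = 1, seed = 1L) {
  if (!length(concentrations))
    abort_striatr("concentrations must be non-empty",
                  "striatr_invalid_parameter")
  if (p_engage < 0 || p_engage > 1)
    abort_striatr("p_engage must be in [0, 1]", "striatr_invalid_parameter")

  k <- length(concentrations)
  with_seed(seed, {
    n_blocks <- ceiling(n_trials / k)
    order_conc <- unlist(lapply(seq_len(n_blocks),
                                function(b) sample(concentrations)))[seq_len(n_trials)]
    onset <- (seq_len(n_trials) - 1) * (access_s + iti_s)
    engaged <- stats::runif(n_trials) < p_engage
    licks <- list()
    for (i in seq_len(n_trials)) {
      if (!engaged[i]) next
      first <- min(stats::rexp(1, 1 / first_lick_mean), access_s * 0.9)
      extra <- stats::rpois(1, lick_rate * (access_s - first))
      lt <- sort(c(first, stats::runif(extra, first, access_s)))
      licks[[length(licks) + 1L]] <- data.frame(
        trial_index = i, time_s = onset[i] + lt)
    }
  })
  trials <- data.frame(trial_index = seq_len(n_trials),
                       concentration = order_conc, onset_s = onset)
  licks <- if (length(licks)) do.call(rbind, licks) else
    data.frame(trial_index = integer(), time_s = numeric())
  rownames(licks) <- NULL
  log <- lick_log(trials, licks)
  attr(log, "ground_truth") <- list(
    n_trials = n_trials, concentrations = concentrations,
    lick_rate = lick_rate, p_engage = p_engage, engaged = engaged,
    access_s = access_s, iti_s = iti_s, seed = seed)
  log
}
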