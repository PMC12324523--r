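# Independent brute-force oracles. These deliberately re-derive each
# quantity from its definition with plain double loops, so they share no
# code path with the package implementations they check.

# All strict local maxima of x with topographic prominence, by exhaustive
# scan: walk outward from each peak to the nearest strictly higher sample
# (or the edge), take the minimum on each side, prominence = peak height
# minus the higher of the two minima.
oracle_peaks <- function(x) {
  n <- length(x)
  idx <- integer(); prom <- numeric()
  for (i in seq_len(n)) {
    if (i == 1L || i == n) next
    if (!(x[i] > x[i - 1L] && x[i] > x[i + 1L])) next
    left_min <- x[i]
    for (j in seq.int(i - 1L, 1L)) {
      if (x[j] > x[i]) break
      if (x[j] < left_min) left_min <- x[j]
    }
    right_min <- x[i]
    for (j in seq.int(i + 1L, n)) {
      if (x[j] > x[i]) break
      if (x[j] < right_min) right_min <- x[j]
    }
    idx <- c(idx, i)
    prom <- c(prom, x[i] - max(left_min, right_min))
  }
  data.frame(index = idx, value = x[idx], prominence = prom)
}

# IS and IV from their definitional sums, double-loop style.
oracle_is <- function(x, p) {
  N <- length(x)
  xbar <- mean(x)
  hsum <- 0
  for (h in seq_len(p)) {
    xh <- x[seq(h, N, by = p)]
    hsum <- hsum + (mean(xh) - xbar)^2
  }
  tot <- 0
  for (i in seq_len(N)) tot <- tot + (x[i] - xbar)^2
  (N * hsum) / (p * tot)
}

oracle_iv <- function(x) {
  N <- length(x)
  xbar <- mean(x)
  dsum <- 0
  for (i in 2:N) dsum <- dsum + (x[i] - x[i - 1])^2
  tot <- 0
  for (i in seq_len(N)) tot <- tot + (x[i] - xbar)^2
  (N * dsum) / ((N - 1) * tot)
}

# Brute-force recount of operant metrics straight off the raw event table.
oracle_operant <- function(sess) {
  ev <- sess$events
  ids <- sort(unique(ev$trial_index))
  pressed <- consumed <- presented <- logical(length(ids))
  first_lat <- reward_lat <- rep(NA_real_, length(ids))
  all_press_lat <- numeric()
  total_presses <- 0L
  for (k in seq_along(ids)) {
    e <- ev[ev$trial_index == ids[k], ]
    ext_t <- Inf
    for (r in seq_len(nrow(e)))
      if (e$event_type[r] == "lever_extension")
        ext_t <- min(ext_t, e$time_s[r])
    presented[k] <- is.finite(ext_t)
    up_t <- Inf; dn_t <- Inf
    for (r in seq_len(nrow(e))) {
      if (e$event_type[r] == "dipper_up") up_t <- min(up_t, e$time_s[r])
    }
    for (r in seq_len(nrow(e)))
      if (e$event_type[r] == "dipper_down" && e$time_s[r] >= up_t)
        dn_t <- min(dn_t, e$time_s[r])
    for (r in seq_len(nrow(e))) {
      if (e$event_type[r] == "lever_press") {
        total_presses <- total_presses + 1L
        pressed[k] <- TRUE
        lat <- e$time_s[r] - ext_t
        all_press_lat <- c(all_press_lat, lat)
        if (is.na(first_lat[k]) || lat < first_lat[k]) first_lat[k] <- lat
      }
      if (e$event_type[r] == "head_entry" &&
          e$time_s[r] >= up_t && e$time_s[r] <= dn_t) {
        consumed[k] <- TRUE
        lat <- e$time_s[r] - up_t
        if (is.na(reward_lat[k]) || lat < reward_lat[k]) reward_lat[k] <- lat
      }
    }
  }
  list(
    pct_lever_press = 100 * sum(pressed) / sum(presented),
    pct_rewarded_trials = 100 * sum(pressed & consumed) / sum(presented),
    latency_first_press_s = mean(first_lat[pressed]),
    latency_mean_press_s = mean(all_press_lat),
    latency_reward_s = mean(reward_lat[consumed & !is.na(reward_lat)]),
    total_presses = total_presses)
}

# A realistic smoothed random trace posing as z-scored dFF (moving-average
# filtered white noise, so it has band-limited structure like 6 Hz
# low-passed photometry).
random_smooth_trace <- function(n, fs = 20, smooth = 9, seed = 1) {
  set.seed(seed)
  z <- as.numeric(stats::filter(rnorm(n + smooth), rep(1 / smooth, smooth),
                                sides = 2))
  z <- z[!is.na(z)][seq_len(n)]
  dff_trace((seq_len(n) - 1) / fs, dff = z, zdff = z,
            session_mean = 0, session_sd = 1, fs = fs)
}
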