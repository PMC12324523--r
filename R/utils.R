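# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_striatr <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "striatr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_striatr(sprintf("`%s` must be a finite numeric scalar", name),
                  "striatr_invalid_parameter")
  if (positive && x <= 0)
    abort_striatr(sprintf("`%s` must be > 0", name),
                  "striatr_invalid_parameter")
  invisible(x)
}

# Run `expr` under a fixed RNG seed without touching the caller's RNG
# stream (all generators take an explicit seed; no global state leaks).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    abort_striatr("`seed` must be a single integer", "striatr_invalid_parameter")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Population standard deviation (divide by n, not n - 1).
sd_pop <- function(x) {
  x <- x[is.finite(x)]
  sqrt(mean((x - mean(x))^2))
}

# Trapezoidal integral of y over x (uniform or non-uniform grid).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# Centered moving average with window of `k` samples (k forced odd).
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- (k - 1L) %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

is_uniform_grid <- function(t, rel_tol = 1e-6) {
  if (length(t) < 2L) return(TRUE)
  dt <- diff(t)
  all(dt > 0) && (max(dt) - min(dt)) <= rel_tol * max(abs(dt))
}
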