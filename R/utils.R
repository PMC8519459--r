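# Internal helpers shared across modules: run-length interval extraction,
# morphological smoothing of logical label sequences, rolling statistics via
# cumulative sums, and trapezoidal integration with interpolated endpoints.

# Runs of TRUE in a logical vector -> data.frame(start, end) of indices
# (inclusive). NA counts as FALSE.
runs_true <- function(b) {
  b[is.na(b)] <- FALSE
  r <- rle(b)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# Morphological closing: set to TRUE any FALSE run of length <= maxgap that
# is flanked by TRUE on both sides.
close_gaps <- function(b, maxgap) {
  b[is.na(b)] <- FALSE
  if (maxgap < 1L) return(b)
  r <- rle(b)
  n <- length(r$values)
  if (n >= 3L) {
    fill <- !r$values & r$lengths <= maxgap &
      seq_len(n) > 1L & seq_len(n) < n
    r$values[fill] <- TRUE
  }
  inverse.rle(r)
}

# Morphological opening: dissolve TRUE runs shorter than minlen.
drop_short_runs <- function(b, minlen) {
  b[is.na(b)] <- FALSE
  r <- rle(b)
  r$values[r$values & r$lengths < minlen] <- FALSE
  inverse.rle(r)
}

# Rolling mean and variance (sample, n-1 denominator) over windows of `width`
# samples starting every `step` samples. NAs inside a window invalidate it
# unless at least `min_frac` of the window is finite, in which case the
# statistics use the finite samples only.
rolling_window_stats <- function(x, width, step, min_frac = 0.9) {
  n <- length(x)
  if (n < width) {
    return(data.frame(start = integer(0), n = integer(0),
                      mean = numeric(0), var = numeric(0)))
  }
  ok <- is.finite(x)
  x0 <- ifelse(ok, x, 0)
  c1 <- c(0, cumsum(x0))
  c2 <- c(0, cumsum(x0^2))
  ck <- c(0L, cumsum(ok))
  starts <- seq.int(1L, n - width + 1L, by = step)
  ends <- starts + width - 1L
  m <- ck[ends + 1L] - ck[starts]
  s1 <- c1[ends + 1L] - c1[starts]
  s2 <- c2[ends + 1L] - c2[starts]
  mu <- s1 / m
  v <- (s2 - s1^2 / m) / (m - 1L)
  v[m < 2L] <- NA_real_
  bad <- m < min_frac * width
  mu[bad] <- NA_real_
  v[bad] <- NA_real_
  # guard tiny negative values from cancellation
  v[!is.na(v) & v < 0] <- 0
  data.frame(start = starts, n = m, mean = mu, var = v)
}

# Cumulative trapezoidal integral of v(t); returns a function-like list used
# by interval_integral(). t must be sorted and strictly increasing.
cumtrapz <- function(t, v) {
  n <- length(t)
  ct <- c(0, cumsum(diff(t) * (v[-n] + v[-1]) / 2))
  list(t = t, v = v, ct = ct)
}

# Integral of v over [t0, t1] with linear interpolation at the endpoints.
# Additive over adjacent intervals by construction.
interval_integral <- function(ci, t0, t1) {
  if (t1 < t0) stop("interval end precedes start")
  tt <- ci$t
  if (t0 < tt[1] || t1 > tt[length(tt)]) {
    stop("integration interval outside series coverage")
  }
  eval_ct <- function(x) {
    j <- findInterval(x, tt)
    j <- min(max(j, 1L), length(tt) - 1L)
    if (x == tt[j]) return(ci$ct[j])
    f <- (x - tt[j]) / (tt[j + 1L] - tt[j])
    vx <- ci$v[j] + f * (ci$v[j + 1L] - ci$v[j])
    ci$ct[j] + (x - tt[j]) * (ci$v[j] + vx) / 2
  }
  eval_ct(t1) - eval_ct(t0)
}

# Trailing running minimum of x over the previous `width` elements
# (including the current one); at the head the window is truncated.
trailing_min <- function(x, width) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- min(x[max(1L, i - width + 1L):i], na.rm = TRUE)
  }
  out[!is.finite(out)] <- NA_real_
  out
}

# Overlap test between one interval and a table of intervals.
overlaps_any <- function(s, e, starts, ends) {
  any(s < ends & e > starts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
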