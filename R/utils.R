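# Internal numerical helpers shared across modules.

# Centered moving average; pads by repeating edge values so the output has
# the same length and no NA.
roll_mean <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L || length(x) < k) return(x)
  pad <- (k - 1L) %/% 2L
  xp <- c(rep(x[1L], pad), x, rep(x[length(x)], pad))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2L))[(pad + 1L):(pad + length(x))]
}

# Odd window size covering `width_s` seconds at `rate` samples/s.
odd_k <- function(width_s, rate, n = Inf) {
  k <- as.integer(round(width_s * rate))
  if (k %% 2L == 0L) k <- k + 1L
  k <- max(3L, k)
  if (is.finite(n)) {
    nmax <- if (n %% 2L == 0L) n - 1L else n
    k <- min(k, max(3L, nmax))
  }
  k
}

# Frame-to-frame noise SD estimate, robust to sparse transients.
noise_sd <- function(x) {
  d <- diff(x)
  stats::mad(d[is.finite(d)]) / sqrt(2)
}

robust_sd <- function(x) stats::mad(x, na.rm = TRUE)

# Sum of x over the half-open circular window [a, b) (1-based sample
# indices into the original series) after a circular left shift of the
# series by each value of `shifts`. Uses a doubled cumulative sum so all
# shifts cost O(1) each.
circ_window_sums <- function(x, a, b, shifts) {
  n <- length(x)
  cs <- c(0, cumsum(c(x, x)))
  len <- b - a
  start <- ((a - 1L + shifts) %% n) + 1L
  cs[start + len] - cs[start]
}

# Two-sided p and null SD for a statistic defined as a linear combination
# of circular-window means, evaluated over all admissible circular shifts.
# `windows` is a list of c(a, b) half-open index windows, `weights` the
# coefficient of each window mean. Shifts closer than `min_shift` samples
# to zero (mod n) are excluded so the null is not contaminated by the
# observed alignment.
shift_null <- function(x, windows, weights, min_shift) {
  n <- length(x)
  shifts <- seq_len(n) - 1L
  keep <- shifts >= min_shift & shifts <= n - min_shift
  stat <- function(sh) {
    v <- 0
    for (j in seq_along(windows)) {
      w <- windows[[j]]
      v <- v + weights[j] * circ_window_sums(x, w[1L], w[2L], sh) / (w[2L] - w[1L])
    }
    v
  }
  obs <- stat(0L)
  null <- stat(shifts[keep])
  list(
    observed = obs,
    p = (1 + sum(abs(null) >= abs(obs))) / (1 + length(null)),
    null_sd = stats::sd(null),
    n_null = length(null)
  )
}

# Linear interpolation resampler with edge extension.
resample_to <- function(t, y, t_out) {
  ok <- is.finite(t) & is.finite(y)
  if (sum(ok) < 2L) return(rep(NA_real_, length(t_out)))
  stats::approx(t[ok], y[ok], xout = t_out, rule = 2)$y
}

# Merge sorted intervals (matrix/data.frame with columns start, end) whose
# gaps are below `gap`; returns a data.frame.
merge_intervals <- function(start, end, gap = 0) {
  if (length(start) == 0L) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  o <- order(start)
  start <- start[o]
  end <- end[o]
  ms <- start[1L]
  me <- end[1L]
  out_s <- numeric(0)
  out_e <- numeric(0)
  for (i in seq_along(start)[-1L]) {
    if (start[i] - me <= gap) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms)
      out_e <- c(out_e, me)
      ms <- start[i]
      me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

# TRUE for every time in `t` falling inside any [start, end) interval.
in_intervals <- function(t, start, end) {
  if (length(start) == 0L) return(rep(FALSE, length(t)))
  hit <- rep(FALSE, length(t))
  for (i in seq_along(start)) hit <- hit | (t >= start[i] & t < end[i])
  hit
}

# Runs of TRUE in a logical vector, as (start index, end index) pairs.
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# Deterministic per-unit seed derived from a master seed; stays within
# 32-bit integer range.
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 16807) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
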