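#' Plethysmography trace container
#'
#' @param samples Calibrated pressure samples (signal units; multiplied by
#'   `calibration` to obtain mL).
#' @param rate Sample rate, samples/s.
#' @param body_mass Animal mass, g (used to normalize tidal volume).
#' @param calibration mL per signal unit.
#' @param t0 Time of the first sample, s.
#' @return Object of class `pleth_trace`.
#' @export
pleth_trace <- function(samples, rate, body_mass = 25, calibration = 1,
                        t0 = 0) {
  stopifnot(rate > 0, body_mass > 0, calibration > 0,
            all(is.finite(samples)))
  structure(
    list(samples = as.numeric(samples), rate = rate, body_mass = body_mass,
         calibration = calibration, t0 = t0),
    class = "pleth_trace"
  )
}

#' @export
print.pleth_trace <- function(x, ...) {
  cat(sprintf("Plethysmography trace: %.1f s at %g Hz, body mass %g g\n",
              length(x$samples) / x$rate, x$rate, x$body_mass))
  invisible(x)
}

pleth_times <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1) / trace$rate
}

# Alternating local extrema of x (indices), pruned so every adjacent
# peak/trough swing is at least `prom[i]` (a per-extremum threshold).
# Removing an adjacent sub-threshold pair preserves alternation.
prune_extrema <- function(x, prom_at) {
  d <- diff(x)
  s <- sign(d)
  s[s == 0] <- 1  # resolve flats to the previous direction
  idx <- which(diff(s) != 0) + 1L
  if (length(idx) < 2L) return(integer(0))
  val <- x[idx]
  repeat {
    if (length(idx) < 2L) break
    swing <- abs(diff(val))
    thr <- pmin(prom_at(idx[-length(idx)]), prom_at(idx[-1L]))
    low <- which(swing < thr)
    if (!length(low)) break
    # remove locally-minimal sub-threshold pairs, non-overlapping
    sw_pad <- c(Inf, swing, Inf)
    loc <- low[swing[low] <= pmin(sw_pad[low], sw_pad[low + 2L])]
    if (!length(loc)) loc <- low[which.min(swing[low])]
    keep_pair <- loc[c(TRUE, diff(loc) >= 2L)]
    drop <- unique(c(keep_pair, keep_pair + 1L))
    idx <- idx[-drop]
    val <- val[-drop]
  }
  idx
}

#' Segment breaths from a plethysmography trace
#'
#' Finds the alternating inspiratory-peak / expiratory-trough sequence by
#' prominence-pruned local extrema on a lightly smoothed, baseline-centred
#' copy of the trace. Tidal volume is the peak-minus-trough excursion of
#' each breath, converted to mL through the calibration factor and
#' normalized to body mass.
#'
#' @param trace A [pleth_trace()].
#' @param min_prominence Minimum peak-to-trough swing retained. `NULL`
#'   (default) adapts to the local signal amplitude: 20% of the rolling
#'   10-s 10th-90th percentile range, so weak sniff breaths survive next
#'   to deep hypercapnic breaths.
#' @param min_cycle_s Shortest credible breath cycle, s.
#' @return A `breath_table` data.frame: one row per breath with `onset`
#'   (inspiration onset, s), `peak_time`, `peak_value`, `trough_time`,
#'   `trough_value` (centred signal units), `vt` (mL), `vt_per_g`
#'   (mL per g body mass), `duration` (s, onset-to-onset), `fr_inst`
#'   (instantaneous breaths/min). A flat trace yields zero rows.
#' @export
detect_breaths <- function(trace, min_prominence = NULL, min_cycle_s = 0.07) {
  stopifnot(inherits(trace, "pleth_trace"))
  x <- trace$samples
  rate <- trace$rate
  n <- length(x)
  if (n < 3L) return(empty_breath_table())

  xs <- roll_mean(x, odd_k(0.02, rate, n))
  center <- stats::runmed(xs, odd_k(2, rate, n))
  xc <- xs - center

  if (is.null(min_prominence)) {
    # local amplitude scale on a 1 s grid
    gt <- seq(1L, n, by = as.integer(max(1, rate)))
    half <- as.integer(5 * rate)
    amp <- vapply(gt, function(i) {
      j <- max(1L, i - half):min(n, i + half)
      diff(stats::quantile(xc[j], c(0.1, 0.9), names = FALSE))
    }, numeric(1))
    amp_at <- function(i) {
      pmax(stats::approx(gt, amp, xout = i, rule = 2)$y * 0.2, 1e-12)
    }
  } else {
    amp_at <- function(i) rep(min_prominence, length(i))
  }

  ext <- prune_extrema(xc, amp_at)
  if (length(ext) < 2L) return(empty_breath_table())

  is_max <- xc[ext] > (xc[pmax(ext - 1L, 1L)] + xc[pmin(ext + 1L, n)]) / 2
  # enforce strict alternation starting from the first maximum
  keep <- logical(length(ext))
  want_max <- TRUE
  for (i in seq_along(ext)) {
    if (is_max[i] == want_max) {
      keep[i] <- TRUE
      want_max <- !want_max
    } else if (keep_better(i, keep, xc, ext, want_max)) {
      # replace the previous extremum with a more extreme same-type one
      keep[max(which(keep))] <- FALSE
      keep[i] <- TRUE
    }
  }
  ext <- ext[keep]
  is_max <- is_max[keep]
  if (!length(ext) || !any(is_max)) return(empty_breath_table())
  if (!is_max[1L]) {
    ext <- ext[-1L]
    is_max <- is_max[-1L]
  }
  if (length(ext) && is_max[length(ext)]) {
    ext <- ext[-length(ext)]
    is_max <- is_max[-length(is_max)]
  }
  if (length(ext) < 2L) return(empty_breath_table())

  peaks <- ext[is_max]
  troughs <- ext[!is_max]  # one following each peak by construction

  # collapse cycles shorter than min_cycle_s (keep the taller peak)
  if (length(peaks) > 1L) {
    repeat {
      gaps <- diff(peaks) / rate
      j <- which(gaps < min_cycle_s)
      if (!length(j)) break
      j <- j[1L]
      drop <- if (xc[peaks[j]] >= xc[peaks[j + 1L]]) j + 1L else j
      peaks <- peaks[-drop]
      troughs <- troughs[-j]  # trough between the merged peaks
    }
  }
  m <- min(length(peaks), length(troughs))
  if (m == 0L) return(empty_breath_table())
  peaks <- peaks[seq_len(m)]
  troughs <- troughs[seq_len(m)]

  t <- pleth_times(trace)
  # inspiration onset: last upward zero-crossing of the centred signal
  # before the peak
  onset <- vapply(seq_len(m), function(i) {
    lo <- if (i == 1L) 1L else troughs[i - 1L]
    j <- peaks[i]
    seg <- lo:j
    below <- which(xc[seg] <= 0)
    if (!length(below)) return(t[lo])
    k <- seg[max(below)]
    if (k < n && xc[k + 1L] > xc[k]) {
      # linear interpolation of the crossing
      t[k] + (0 - xc[k]) / (xc[k + 1L] - xc[k]) / rate
    } else t[k]
  }, numeric(1))

  vt_signal <- xc[peaks] - xc[troughs]
  vt <- vt_signal * trace$calibration
  dur <- c(diff(onset), NA_real_)
  out <- data.frame(
    onset = onset,
    peak_time = t[peaks], peak_value = xc[peaks],
    trough_time = t[troughs], trough_value = xc[troughs],
    vt = vt, vt_per_g = vt / trace$body_mass,
    duration = dur, fr_inst = 60 / dur
  )
  class(out) <- c("breath_table", "data.frame")
  attr(out, "rate") <- rate
  out
}

empty_breath_table <- function() {
  out <- data.frame(
    onset = numeric(0), peak_time = numeric(0), peak_value = numeric(0),
    trough_time = numeric(0), trough_value = numeric(0), vt = numeric(0),
    vt_per_g = numeric(0), duration = numeric(0), fr_inst = numeric(0)
  )
  class(out) <- c("breath_table", "data.frame")
  out
}

# helper for alternation repair: TRUE if extremum i is the same type the
# scan is NOT waiting for but more extreme than the last kept one
keep_better <- function(i, keep, xc, ext, want_max) {
  k <- which(keep)
  if (!length(k)) return(FALSE)
  last <- k[length(k)]
  if (want_max) {
    # waiting for a max, found another min: keep the deeper one
    xc[ext[i]] < xc[ext[last]]
  } else {
    xc[ext[i]] > xc[ext[last]]
  }
}

#' Rolling ventilation metrics
#'
#' Computes tidal volume, respiratory frequency and minute ventilation on
#' a uniform time grid from a breath table. Within each centred window,
#' `V_T` is the mean per-breath tidal volume, `fR` is 60 divided by the
#' mean cycle duration, and minute ventilation is defined as their exact
#' product `V_E = V_T x fR` at every grid point.
#'
#' @param breaths A `breath_table` from [detect_breaths()].
#' @param window_s Rolling window width, s; must cover at least one
#'   typical cycle.
#' @param dt Grid step, s.
#' @param end_time Optional end of the grid, s (default: last breath end).
#' @return A `ventilation_series` data.frame with columns `time`, `vt`
#'   (mL/g), `fr` (breaths/min), `ve` (mL/g/min); the breath table is
#'   attached as an attribute for event detectors.
#' @export
compute_ventilation <- function(breaths, window_s = 2, dt = 0.25,
                                end_time = NULL) {
  stopifnot(inherits(breaths, "breath_table"))
  if (nrow(breaths) < 1L) stop("need at least one breath")
  med_cycle <- stats::median(breaths$duration, na.rm = TRUE)
  if (is.finite(med_cycle) && window_s < med_cycle) {
    stop("window_s is shorter than one breathing cycle")
  }
  b <- breaths[is.finite(breaths$duration), , drop = FALSE]
  end_time <- end_time %||% (max(breaths$onset) + med_cycle)
  grid <- seq(0, end_time, by = dt)

  cs_dur <- c(0, cumsum(b$duration))
  cs_vt <- c(0, cumsum(b$vt_per_g))
  lo <- findInterval(grid - window_s / 2, b$onset, left.open = TRUE) + 1L
  hi <- findInterval(grid + window_s / 2, b$onset)
  cnt <- pmax(hi - lo + 1L, 0L)
  vt <- fr <- rep(NA_real_, length(grid))
  ok <- cnt > 0L
  vt[ok] <- (cs_vt[hi[ok] + 1L] - cs_vt[lo[ok]]) / cnt[ok]
  fr[ok] <- 60 * cnt[ok] / (cs_dur[hi[ok] + 1L] - cs_dur[lo[ok]])
  vt <- resample_to(grid, vt, grid)
  fr <- resample_to(grid, fr, grid)

  out <- data.frame(time = grid, vt = vt, fr = fr, ve = vt * fr)
  class(out) <- c("ventilation_series", "data.frame")
  attr(out, "breaths") <- breaths
  attr(out, "window_s") <- window_s
  out
}

#' @export
print.ventilation_series <- function(x, ...) {
  cat(sprintf(
    "Ventilation series: %.0f s, mean fR %.0f breaths/min, mean V_E %.3g mL/g/min\n",
    max(x$time), mean(x$fr, na.rm = TRUE), mean(x$ve, na.rm = TRUE)
  ))
  invisible(x)
}
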