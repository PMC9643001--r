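#' Event-triggered average of a calcium trace
#'
#' Aligns dF/F segments to behavioural event onsets, subtracts each
#' segment's value at the left window edge, and averages pointwise (the
#' "spike triggered average" of the figure legends). Events whose window
#' is clipped by the recording edges are dropped and counted.
#'
#' @param trace A [calcium_trace()] with `dff` computed.
#' @param events An `event_series` or numeric vector of onset times, s.
#' @param window_s Half-width of the symmetric lag window, s.
#' @return Object of class `triggered_average`: `lag` (s, includes 0),
#'   `mean`, `sd`, `n` (events used), `n_dropped`, `segments`
#'   (events x lags matrix).
#' @export
triggered_average <- function(trace, events, window_s = 2) {
  stopifnot(inherits(trace, "calcium_trace"))
  if (is.null(trace$dff)) stop("compute dF/F first")
  onsets <- if (is.data.frame(events)) events$onset else as.numeric(events)
  t <- frame_times(trace)
  lag <- seq(-window_s, window_s, by = 1 / trace$rate)
  if (!any(lag == 0)) lag <- sort(c(lag, 0))
  usable <- onsets[onsets + lag[1L] >= t[1L] &
                     onsets + lag[length(lag)] <= t[length(t)]]
  if (!length(usable)) stop("no event has a full window inside the record")
  seg <- t(vapply(usable, function(e) {
    s <- resample_to(t, as.numeric(trace$dff), e + lag)
    s - s[1L]
  }, numeric(length(lag))))
  structure(list(
    lag = lag,
    mean = colMeans(seg),
    sd = apply(seg, 2L, stats::sd),
    n = length(usable),
    n_dropped = length(onsets) - length(usable),
    segments = seg
  ), class = "triggered_average")
}

#' @export
print.triggered_average <- function(x, ...) {
  cat(sprintf(
    "Triggered average: %d events (%d dropped), peak %.3f dF/F at lag %.2f s\n",
    x$n, x$n_dropped, max(x$mean), x$lag[which.max(x$mean)]
  ))
  invisible(x)
}

#' @export
plot.triggered_average <- function(x, ...) {
  graphics::matplot(x$lag, t(x$segments), type = "l", lty = 1,
                    col = grDevices::adjustcolor("grey50", 0.4),
                    xlab = "lag from event onset (s)", ylab = "dF/F", ...)
  graphics::lines(x$lag, x$mean, col = "#5E355E", lwd = 2)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Onset latency of calcium activity relative to behavioural events
#'
#' For each behavioural event, finds the nearest calcium transient onset
#' within the window and reports the lead \code{event onset - Ca onset}
#' (positive = calcium precedes the event). Transient onsets are the
#' last sub-threshold frame before the dF/F threshold crossing, the same
#' rule as [detect_transients()]. Events with no onset in the window are
#' skipped and counted. When a protocol is supplied, leads are also
#' summarized per CO2 level (the pF_L lead shortens with inspired CO2).
#'
#' @param trace A [calcium_trace()] with `dff`.
#' @param events `event_series` or numeric onsets, s.
#' @param onset_threshold Robust z threshold of the transient detector.
#' @param window_s Matching half-window, s.
#' @param protocol Optional [gas_protocol()] for per-level summaries.
#' @param transients Optional precomputed `transient_table`.
#' @param bin_s Histogram bin width, s.
#' @return Object of class `latency_estimate`: per-event `leads` (s),
#'   `n_events`, `n_matched`, `n_skipped`, `coverage`, `mean_lead`,
#'   `median_lead`, `sign_p` (one-sided sign test against zero lead),
#'   `histogram` and optional `per_level` data.frame.
#' @export
onset_latency <- function(trace, events, onset_threshold = 3, window_s = 2,
                          protocol = NULL, transients = NULL, bin_s = 0.1) {
  stopifnot(inherits(trace, "calcium_trace"))
  onsets_b <- if (is.data.frame(events)) events$onset else as.numeric(events)
  transients <- transients %||%
    detect_transients(trace, z_threshold = onset_threshold)
  ca <- transients$onset
  leads <- rep(NA_real_, length(onsets_b))
  if (length(ca)) {
    for (i in seq_along(onsets_b)) {
      d <- onsets_b[i] - ca
      ok <- abs(d) <= window_s
      if (any(ok)) leads[i] <- d[ok][which.min(abs(d[ok]))]
    }
  }
  matched <- is.finite(leads)
  ld <- leads[matched]
  n_pos <- sum(ld > 0)
  n_eff <- sum(ld != 0)
  sign_p <- if (n_eff > 0) {
    stats::binom.test(n_pos, n_eff, alternative = "greater")$p.value
  } else NA_real_
  brk <- seq(-ceiling(window_s / bin_s) * bin_s,
             ceiling(window_s / bin_s) * bin_s, by = bin_s)
  hst <- if (length(ld)) graphics::hist(ld, breaks = brk, plot = FALSE)
  per_level <- NULL
  if (!is.null(protocol) && length(ld)) {
    lev <- co2_at(protocol, onsets_b[matched])
    per_level <- do.call(rbind, lapply(sort(unique(lev)), function(l) {
      data.frame(co2 = l, n = sum(lev == l),
                 mean_lead = mean(ld[lev == l]),
                 median_lead = stats::median(ld[lev == l]))
    }))
  }
  structure(list(
    leads = leads, n_events = length(onsets_b), n_matched = sum(matched),
    n_skipped = sum(!matched),
    coverage = if (length(onsets_b)) sum(matched) / length(onsets_b) else NA_real_,
    mean_lead = if (length(ld)) mean(ld) else NA_real_,
    median_lead = if (length(ld)) stats::median(ld) else NA_real_,
    sign_p = sign_p, histogram = hst, per_level = per_level
  ), class = "latency_estimate")
}

#' @export
print.latency_estimate <- function(x, ...) {
  cat(sprintf(
    "Onset latency: %d/%d events matched, mean lead %.2f s (median %.2f, sign p %.3g)\n",
    x$n_matched, x$n_events, x$mean_lead, x$median_lead, x$sign_p
  ))
  if (!is.null(x$per_level)) print(x$per_level)
  invisible(x)
}

#' Correlation between calcium activity and a ventilation variable
#'
#' Resamples dF/F and the chosen ventilation variable onto a common 2-Hz
#' grid, smooths both, and scans the cross-correlation over lags within
#' `max_lag_s`. Positive best lag means the calcium signal follows the
#' ventilation variable. Significance comes from a circular-shift null:
#' the same maximum-|r| statistic evaluated at every admissible circular
#' offset of the calcium series, which preserves the autocorrelation of
#' both series (the null is deterministic: all offsets at least
#' `min_shift_s` from alignment are used).
#'
#' @param trace A [calcium_trace()] with `dff`.
#' @param vent A [compute_ventilation()] series.
#' @param variable `"V_T"`, `"fR"` or `"V_E"` (case-insensitive aliases
#'   `vt`, `fr`, `ve`).
#' @param max_lag_s Lag scan half-width, s.
#' @param detrend `"none"`, or `"epoch"` to remove a per-epoch linear
#'   trend from both series (isolates breath-to-breath variability from
#'   the stepped CO2 response; requires `protocol`).
#' @param protocol [gas_protocol()] for epoch detrending.
#' @param smooth_s Boxcar smoothing applied to both series, s.
#' @param grid_hz Common grid rate, Hz.
#' @param min_shift_s Minimum circular offset entering the null, s.
#' @param window Optional `c(start, end)` restriction, s.
#' @return A list: `r` (signed correlation at the best lag), `best_lag`
#'   (s), `p`, `r_by_lag` (data.frame), `variable`, `constant` (TRUE when
#'   either series was flat and the correlation is undefined).
#' @export
ventilation_correlation <- function(trace, vent, variable = c("V_T", "fR", "V_E"),
                                    max_lag_s = 5, detrend = c("none", "epoch"),
                                    protocol = NULL, smooth_s = 5,
                                    grid_hz = 2, min_shift_s = 20,
                                    window = NULL) {
  stopifnot(inherits(trace, "calcium_trace"),
            inherits(vent, "ventilation_series"))
  detrend <- match.arg(detrend)
  v <- tolower(variable[1L])
  col <- switch(v, "v_t" = , "vt" = "vt", "fr" = "fr",
                "v_e" = , "ve" = "ve",
                stop("unknown ventilation variable: ", variable[1L]))
  tt <- frame_times(trace)
  lo <- max(min(tt), min(vent$time))
  hi <- min(max(tt), max(vent$time))
  if (!is.null(window)) {
    lo <- max(lo, window[1L])
    hi <- min(hi, window[2L])
  }
  if (hi - lo < 4 * max_lag_s) stop("overlapping support too short")
  grid <- seq(lo, hi, by = 1 / grid_hz)
  x <- resample_to(vent$time, vent[[col]], grid)
  y <- resample_to(tt, as.numeric(trace$dff), grid)
  k <- odd_k(smooth_s, grid_hz, length(grid))
  x <- roll_mean(x, k)
  y <- roll_mean(y, k)
  if (detrend == "epoch") {
    if (is.null(protocol)) stop("epoch detrending needs a protocol")
    w <- epoch_windows(protocol)
    for (i in seq_len(nrow(w))) {
      sel <- grid >= w$start[i] & grid < w$end[i]
      if (sum(sel) > 3L) {
        g <- grid[sel]
        x[sel] <- stats::resid(stats::lm(x[sel] ~ g))
        y[sel] <- stats::resid(stats::lm(y[sel] ~ g))
      }
    }
  }
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
    return(list(r = NA_real_, best_lag = NA_real_, p = NA_real_,
                r_by_lag = NULL, variable = col, constant = TRUE))
  }
  xc <- (x - mean(x)) / stats::sd(x)
  yc <- (y - mean(y)) / stats::sd(y)
  n <- length(xc)
  # circular cross-correlation at every offset k: mean of xc[i] * yc[i+k]
  cc <- Re(stats::fft(Conj(stats::fft(xc)) * stats::fft(yc),
                      inverse = TRUE)) / n^2
  lag_steps <- seq(-round(max_lag_s * grid_hz), round(max_lag_s * grid_hz))
  at <- function(kk) cc[(kk %% n) + 1L]
  r_lags <- at(lag_steps)
  obs <- max(abs(r_lags))
  best <- lag_steps[which.max(abs(r_lags))]

  min_shift <- as.integer(min_shift_s * grid_hz)
  shifts <- seq_len(n) - 1L
  shifts <- shifts[shifts >= min_shift & shifts <= n - min_shift]
  null_max <- vapply(shifts, function(s) max(abs(at(s + lag_steps))),
                     numeric(1))
  p <- (1 + sum(null_max >= obs)) / (1 + length(null_max))
  list(
    r = r_lags[which.max(abs(r_lags))],
    best_lag = best / grid_hz,
    p = p,
    r_by_lag = data.frame(lag = lag_steps / grid_hz, r = r_lags),
    variable = col,
    constant = FALSE
  )
}
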