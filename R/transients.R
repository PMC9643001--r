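#' Detect calcium transients
#'
#' Flags events where dF/F exceeds a robust z threshold above a running
#' baseline (median filter). The noise scale is estimated from
#' frame-to-frame differences, so sparse transients do not inflate it.
#' Because a transient has a fast rise, a supra-threshold excursion is
#' split wherever a further rapid-rise burst (slope above `slope_z`
#' robust SDs of the frame-to-frame slope) lifts the signal by at least
#' twice the detection threshold: transients riding on a predecessor's
#' decay are separated by their own rise. Events so close that their
#' rises fuse into one slope excursion remain merged (documented
#' behaviour).
#'
#' @param trace A [calcium_trace()] with `dff` computed.
#' @param z_threshold Robust z threshold (default 3).
#' @param baseline_width_s Running-median window, s.
#' @param min_width_s Minimum supra-threshold duration, s.
#' @param merge_gap_s Sub-threshold gaps shorter than this merge runs.
#' @param smooth_frames Boxcar pre-smoothing width, frames (odd; reduces
#'   single-frame noise without shifting the centred onset).
#' @param slope_z Robust z threshold on the frame-to-frame slope used to
#'   split fused transients.
#' @return A `transient_table` data.frame: `onset` (time of the last
#'   sub-threshold frame before the crossing, s), `peak_time`, `amplitude`
#'   (dF/F above the running baseline at the peak), `width` (s);
#'   attributes `sigma` (noise SD) and `baseline` (running baseline).
#' @export
detect_transients <- function(trace, z_threshold = 3, baseline_width_s = 30,
                              min_width_s = 0.15, merge_gap_s = 0.2,
                              smooth_frames = 3L, slope_z = 3.5) {
  stopifnot(inherits(trace, "calcium_trace"))
  if (is.null(trace$dff)) stop("compute dF/F first")
  raw <- as.numeric(trace$dff)
  sigma <- max(noise_sd(raw), 1e-12)  # per-frame noise, before smoothing
  dff <- roll_mean(raw, smooth_frames)
  n <- length(dff)
  rate <- trace$rate
  t <- frame_times(trace)

  base <- stats::runmed(dff, odd_k(baseline_width_s, rate, n))
  resid <- dff - base
  thr <- z_threshold * sigma

  above <- resid > thr
  if (!any(above)) return(empty_transient_table(sigma, base))

  runs <- true_runs(above)
  # merge runs separated by short sub-threshold gaps
  iv <- merge_intervals(runs$start, runs$end + 1L,
                        gap = max(1, round(merge_gap_s * rate)))
  iv$end <- iv$end - 1L
  min_w <- max(2L, as.integer(round(min_width_s * rate)))
  iv <- iv[iv$end - iv$start + 1L >= min_w, , drop = FALSE]
  if (!nrow(iv)) return(empty_transient_table(sigma, base))

  ds <- c(0, diff(dff))
  sigma_ds <- max(stats::mad(ds), 1e-12)
  slope_thr <- slope_z * sigma_ds

  onset_idx <- integer(0)
  peak_idx <- integer(0)
  amp <- width <- numeric(0)
  for (i in seq_len(nrow(iv))) {
    seg <- iv$start[i]:iv$end[i]
    rising <- true_runs(ds[seg] > slope_thr)
    rising <- rising[rising$end - rising$start >= 1L, , drop = FALSE]
    # boundaries: starts of later rise bursts that lift the signal enough
    bnd <- integer(0)
    if (nrow(rising) > 1L) {
      for (j in 2:nrow(rising)) {
        pre <- max(1L, rising$start[j] - 1L)
        gain <- resid[seg][rising$end[j]] - resid[seg][pre]
        if (gain >= 2 * thr) bnd <- c(bnd, rising$start[j])
      }
    }
    starts <- c(1L, bnd)
    ends <- c(bnd - 1L, length(seg))
    for (j in seq_along(starts)) {
      sub <- seg[starts[j]:ends[j]]
      pk <- sub[which.max(resid[sub])]
      on <- if (j == 1L) max(1L, iv$start[i] - 1L) else seg[starts[j] - 1L]
      onset_idx <- c(onset_idx, on)
      peak_idx <- c(peak_idx, pk)
      amp <- c(amp, resid[pk] - max(0, resid[on]))
      width <- c(width, length(sub) / rate)
    }
  }
  out <- data.frame(
    onset = t[onset_idx],
    peak_time = t[peak_idx],
    amplitude = amp,
    width = width
  )
  out <- out[order(out$onset), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("transient_table", "data.frame")
  attr(out, "sigma") <- sigma
  attr(out, "baseline") <- base
  out
}

empty_transient_table <- function(sigma = NA_real_, base = NULL) {
  out <- data.frame(onset = numeric(0), peak_time = numeric(0),
                    amplitude = numeric(0), width = numeric(0))
  class(out) <- c("transient_table", "data.frame")
  attr(out, "sigma") <- sigma
  attr(out, "baseline") <- base
  out
}

#' Fit transient kinetics
#'
#' Estimates the 10-90% rise time of the onset limb and the exponential
#' time constant of the post-peak decay for a single transient. The decay
#' fit starts four rise times past the peak, where the residual rise
#' component (which falls on its own, much faster time scale) is below a
#' few permille of the decay and cannot bias tau, and runs to the point
#' where the transient has decayed to 10% of its amplitude or the next
#' event begins. The baseline offset of the fit is bounded to a fraction
#' of the amplitude so it cannot trade off against tau on short windows.
#'
#' @param trace A [calcium_trace()] with `dff`.
#' @param event One row of a `transient_table` (or a list with `onset`,
#'   `peak_time`, `amplitude`).
#' @param next_onset Onset of the following event, s (limits the fit
#'   window); `Inf` if none.
#' @return A list: `rise_time` (s), `decay_tau` (s), `gof` (R^2 of the
#'   decay fit), `converged`. Non-convergent fits return `NA` taus with
#'   `converged = FALSE` and are excluded from kinetics summaries.
#' @export
fit_transient_kinetics <- function(trace, event, next_onset = Inf) {
  stopifnot(inherits(trace, "calcium_trace"))
  t <- frame_times(trace)
  dff <- as.numeric(trace$dff)
  base <- stats::median(dff[t >= event$onset - 2 & t <= event$onset])
  amp <- event$amplitude

  failed <- list(rise_time = NA_real_, decay_tau = NA_real_,
                 gof = NA_real_, converged = FALSE)

  # rise: first crossings of 10% and 90% amplitude between onset and peak
  seg <- which(t >= event$onset & t <= event$peak_time + 0.5 / trace$rate)
  if (length(seg) < 2L || !is.finite(amp) || amp <= 0) return(failed)
  y <- dff[seg] - base
  cross <- function(level) {
    j <- which(y >= level)[1L]
    if (is.na(j)) return(NA_real_)
    if (j == 1L) return(t[seg[1L]])
    t[seg[j - 1L]] + (level - y[j - 1L]) / (y[j] - y[j - 1L]) / trace$rate
  }
  t10 <- cross(0.1 * amp)
  t90 <- cross(0.9 * amp)
  rise_time <- t90 - t10
  if (!is.finite(rise_time) || rise_time <= 0) return(failed)

  # decay window: 4 rise times past the peak, down to 5% of amplitude.
  # A centred boxcar of an exponential is a rescaled exponential with the
  # same tau, so fitting the lightly smoothed segment is unbiased and
  # nearly halves the noise.
  dffs <- roll_mean(dff, 3L)
  d0 <- event$peak_time + min(max(4 * rise_time, 0.4), 1.2)
  dseg <- which(t >= d0 & t < next_onset)
  yd <- dffs[dseg] - base
  stop_at <- which(yd < 0.05 * amp)[1L]
  if (!is.na(stop_at) && stop_at > 5L) dseg <- dseg[seq_len(stop_at)]
  if (length(dseg) < 6L) return(failed)
  td <- t[dseg] - d0
  yd <- dffs[dseg] - base

  tau0 <- {
    j <- which(yd < yd[1L] * exp(-1))[1L]
    if (is.na(j)) max(td) else max(td[j], 2 / trace$rate)
  }
  # physical bound: residual baseline error comes from slow drift and the
  # running-median estimate, a few percent of F0, not a fraction of a
  # large amplitude
  c0_max <- max(0.02, 0.03 * amp)
  fit <- tryCatch(
    minpack.lm::nlsLM(yd ~ a * exp(-td / tau) + c0,
                      start = list(a = yd[1L], tau = tau0, c0 = 0),
                      lower = c(1e-9, 1e-3, -c0_max),
                      upper = c(Inf, Inf, c0_max),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(failed)
  tau <- stats::coef(fit)[["tau"]]
  res <- stats::resid(fit)
  gof <- 1 - sum(res^2) / max(sum((yd - mean(yd))^2), 1e-300)
  if (!is.finite(tau) || tau <= 0) return(failed)
  list(rise_time = rise_time, decay_tau = tau, gof = gof, converged = TRUE)
}

#' Kinetics of all sufficiently isolated transients
#'
#' Convenience wrapper: fits [fit_transient_kinetics()] for every event
#' whose window is free of overlap with the next event, and reports the
#' epoch each event falls into when a protocol is supplied. Used for the
#' transient-shape invariance check (kinetics before vs during vs after
#' hypercapnia).
#'
#' @param trace A [calcium_trace()] with `dff`.
#' @param transients A `transient_table`; default detects with z = 3.
#' @param protocol Optional [gas_protocol()] for epoch assignment.
#' @param min_isolation_s Required gap to the next onset, s.
#' @return Data.frame with `onset`, `rise_time`, `decay_tau`, `gof`,
#'   `converged` and (with a protocol) `co2`.
#' @export
transient_kinetics <- function(trace, transients = NULL, protocol = NULL,
                               min_isolation_s = 3) {
  transients <- transients %||% detect_transients(trace)
  n <- nrow(transients)
  if (!n) {
    return(data.frame(onset = numeric(0), rise_time = numeric(0),
                      decay_tau = numeric(0), gof = numeric(0),
                      converged = logical(0)))
  }
  nxt <- c(transients$onset[-1L], Inf)
  rows <- lapply(seq_len(n), function(i) {
    if (nxt[i] - transients$peak_time[i] < min_isolation_s) return(NULL)
    k <- fit_transient_kinetics(trace, transients[i, ], next_onset = nxt[i])
    data.frame(onset = transients$onset[i], rise_time = k$rise_time,
               decay_tau = k$decay_tau, gof = k$gof, converged = k$converged)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(onset = numeric(0), rise_time = numeric(0),
                      decay_tau = numeric(0), gof = numeric(0),
                      converged = logical(0))
  }
  if (!is.null(protocol) && nrow(out)) out$co2 <- co2_at(protocol, out$onset)
  out
}
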