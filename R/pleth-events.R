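#' Behavioural event series
#'
#' @param type Event type: `"sniff"`, `"expiration"` or `"movement"`.
#' @param onset Event onset times, s.
#' @param duration Event durations, s (0 for point events).
#' @param magnitude Per-event magnitude (detector-specific units).
#' @return An `event_series` data.frame sorted by onset.
#' @export
event_series <- function(type, onset, duration = rep(0, length(onset)),
                         magnitude = rep(NA_real_, length(onset))) {
  stopifnot(all(duration >= 0))
  o <- order(onset)
  out <- data.frame(type = rep(type, length(onset))[o], onset = onset[o],
                    duration = duration[o], magnitude = magnitude[o],
                    stringsAsFactors = FALSE)
  class(out) <- c("event_series", "data.frame")
  out
}

#' Detect sniff bouts from the ventilation series
#'
#' A sniff bout is a maximal run in which respiratory frequency exceeds a
#' threshold for at least `min_duration_s`. The default threshold is
#' `factor` times the running eupneic median fR (median over
#' `eupnea_window_s`), which tracks the CO2-driven baseline so a stepped
#' protocol does not trigger false bouts. Bout onsets are refined to the
#' first supra-threshold breath.
#'
#' @param vent A [compute_ventilation()] series (carries its breath table).
#' @param fr_threshold Absolute fR threshold in breaths/min, or `NULL`
#'   (default) for the adaptive `factor` x running-median rule. A
#'   threshold of 0 degenerately returns one bout spanning the record.
#' @param factor Multiple of the running eupneic median fR.
#' @param min_duration_s Minimum supra-threshold duration, s.
#' @param eupnea_window_s Width of the running-median window, s.
#' @param movement Optional `event_series` of movement bouts; apparent
#'   fR surges overlapping a bout are artefacts and are discarded.
#' @return An `event_series` of sniff bouts (onset, duration, magnitude =
#'   peak fR in the bout, breaths/min).
#' @export
detect_sniff_bouts <- function(vent, fr_threshold = NULL, factor = 2,
                               min_duration_s = 0.5, eupnea_window_s = 60,
                               movement = NULL) {
  stopifnot(inherits(vent, "ventilation_series"))
  dt <- vent$time[2L] - vent$time[1L]
  fr <- vent$fr
  if (is.null(fr_threshold)) {
    k <- odd_k(eupnea_window_s, 1 / dt, length(fr))
    thr <- factor * stats::runmed(fr, k)
  } else {
    thr <- rep(fr_threshold, length(fr))
  }
  supra <- fr > thr
  supra[!is.finite(fr)] <- FALSE
  if (all(thr <= 0)) supra <- rep(TRUE, length(fr))
  runs <- true_runs(supra)
  if (!nrow(runs)) return(event_series("sniff", numeric(0)))
  iv <- merge_intervals(vent$time[runs$start], vent$time[runs$end] + dt,
                        gap = 0.5)
  keep <- (iv$end - iv$start) >= min_duration_s
  if (!is.null(movement) && nrow(movement)) {
    for (i in seq_len(nrow(iv))) {
      ovl <- pmin(iv$end[i], movement$onset + movement$duration + 0.5) -
        pmax(iv$start[i], movement$onset - 0.5)
      if (any(ovl > 0)) keep[i] <- FALSE
    }
  }
  iv <- iv[keep, , drop = FALSE]
  if (!nrow(iv)) return(event_series("sniff", numeric(0)))

  breaths <- attr(vent, "breaths")
  onset <- iv$start
  mag <- rep(NA_real_, nrow(iv))
  w <- attr(vent, "window_s") %||% 2
  for (i in seq_len(nrow(iv))) {
    sel <- which(vent$time >= iv$start[i] & vent$time < iv$end[i])
    if (length(sel)) mag[i] <- max(fr[sel])
    if (!is.null(breaths) && nrow(breaths)) {
      thr_i <- stats::approx(vent$time, thr, xout = iv$start[i], rule = 2)$y
      near <- which(breaths$onset >= iv$start[i] - w &
                      breaths$onset <= iv$end[i] &
                      is.finite(breaths$fr_inst) &
                      breaths$fr_inst > thr_i)
      if (length(near)) onset[i] <- breaths$onset[near[1L]]
    }
  }
  event_series("sniff", onset, pmax(iv$end - onset, 0), mag)
}

#' Detect active expiration events
#'
#' Active expiration recruits expiratory muscles and produces an enlarged
#' expiratory trough. Because tidal volume itself grows with CO2, the
#' statistic is scale-free: the trough-depth-to-peak-height ratio of each
#' breath, compared by robust z-score against the baseline-epoch
#' distribution of that ratio. Event onset is the post-peak zero crossing
#' of the breath (start of expiratory flow).
#'
#' @param trace The [pleth_trace()] the breaths came from.
#' @param breaths `breath_table` from [detect_breaths()].
#' @param trough_z_threshold Robust z threshold (z is floored at 0, so a
#'   threshold of 0 degenerately flags every breath).
#' @param baseline_window Optional `c(start, end)` of the 0% CO2 baseline,
#'   s. When absent the whole record is used and the result is flagged.
#' @param movement Optional `event_series` of movement bouts; breaths
#'   whose peak falls inside a bout are artefact-contaminated and
#'   excluded from candidacy.
#' @return An `event_series` of expirations (magnitude = robust z of the
#'   trough ratio); attribute `baseline` is `"window"` or
#'   `"whole-record"`.
#' @export
detect_active_expiration <- function(trace, breaths, trough_z_threshold = 4,
                                     baseline_window = NULL,
                                     movement = NULL) {
  stopifnot(inherits(trace, "pleth_trace"), inherits(breaths, "breath_table"))
  if (!nrow(breaths)) {
    out <- event_series("expiration", numeric(0))
    attr(out, "baseline") <- "whole-record"
    return(out)
  }
  ratio <- -breaths$trough_value / pmax(breaths$peak_value, 1e-12)
  if (!is.null(baseline_window)) {
    sel <- breaths$onset >= baseline_window[1L] &
      breaths$onset < baseline_window[2L]
    base_src <- "window"
    if (sum(sel) < 10L) {
      sel <- rep(TRUE, length(ratio))
      base_src <- "whole-record"
    }
  } else {
    sel <- rep(TRUE, length(ratio))
    base_src <- "whole-record"
  }
  med <- stats::median(ratio[sel])
  # scale floored at a quarter of the median ratio so measurement noise on
  # individual extrema cannot masquerade as expiratory recruitment
  sc <- max(stats::mad(ratio[sel]), 0.25 * abs(med), 1e-12)
  z <- pmax(0, (ratio - med) / sc)
  if (trough_z_threshold <= 0) {
    hit <- seq_len(nrow(breaths))  # degenerate: every breath flagged
  } else {
    # expiratory recruitment also deepens the absolute trough; a local
    # depth guard rejects small sniff breaths whose ratio is noisy
    depth <- -breaths$trough_value
    if (length(depth) >= 3L) {
      k <- min(63L, if (length(depth) %% 2L == 0L) length(depth) - 1L
               else length(depth))
      loc_med <- stats::runmed(depth, k)
    } else {
      loc_med <- rep(stats::median(depth), length(depth))
    }
    total_t <- length(trace$samples) / trace$rate
    keep <- z >= trough_z_threshold & depth > 1.5 * loc_med &
      breaths$onset > trace$t0 + 1 &
      breaths$trough_time < trace$t0 + total_t - 1
    if (!is.null(movement) && nrow(movement)) {
      # pad: breath segmentation is unreliable right at bout edges too
      keep <- keep & !in_intervals(breaths$peak_time, movement$onset - 0.5,
                                   movement$onset + movement$duration + 0.5)
    }
    hit <- which(keep)
  }

  # onset: first downward zero crossing of the centred signal after the peak
  x <- trace$samples
  xs <- roll_mean(x, odd_k(0.02, trace$rate, length(x)))
  center <- stats::runmed(xs, odd_k(2, trace$rate, length(x)))
  xc <- xs - center
  t <- pleth_times(trace)
  onset <- vapply(hit, function(i) {
    j0 <- max(1L, as.integer((breaths$peak_time[i] - trace$t0) * trace$rate))
    j1 <- min(length(x),
              as.integer((breaths$trough_time[i] - trace$t0) * trace$rate) + 1L)
    if (j1 <= j0) return(breaths$peak_time[i])
    seg <- j0:j1
    below <- which(xc[seg] <= 0)
    if (!length(below)) return(breaths$peak_time[i])
    k <- seg[below[1L]]
    if (k > 1L && xc[k - 1L] > 0) {
      t[k - 1L] + xc[k - 1L] / (xc[k - 1L] - xc[k]) / trace$rate
    } else t[k]
  }, numeric(1))
  dur <- pmax(breaths$trough_time[hit] - onset, 0)
  out <- event_series("expiration", onset, dur, z[hit])
  attr(out, "baseline") <- base_src
  out
}

#' Movement sonogram and bout detection
#'
#' Short-time spectral power map of a uniformly sampled channel, with
#' movement bouts defined as intervals where broadband power exceeds a
#' robust z threshold. Breathing concentrates below ~10-15 Hz even while
#' sniffing, whereas movement artefacts are broadband, so the default band
#' of 20-80 Hz isolates them. The detector is channel-agnostic: run it on
#' the WBP trace and on an external movement channel and the two bout sets
#' can be cross-compared.
#'
#' @param channel Numeric samples, or a [pleth_trace()].
#' @param rate Sample rate, samples/s (taken from the trace if given one).
#' @param window_s STFT window length, s.
#' @param band `c(lo, hi)` frequency band, Hz.
#' @param z_threshold Robust z threshold on log band power; bouts must
#'   additionally exceed the quiet floor by 1.5 decades and last at
#'   least `min_duration_s`.
#' @param min_duration_s Minimum bout duration, s.
#' @return A list: `spectrogram` (`time`, `freq`, `power` matrix
#'   freq x time), `band_power` (log power per time bin), `events`
#'   (`event_series` of movement bouts, magnitude = peak z).
#' @export
movement_sonogram <- function(channel, rate = NULL, window_s = 0.25,
                              band = c(20, 80), z_threshold = 4,
                              min_duration_s = 0.3) {
  if (inherits(channel, "pleth_trace")) {
    rate <- channel$rate
    channel <- channel$samples
  }
  stopifnot(!is.null(rate), rate > 0)
  n <- length(channel)
  if (window_s * rate > n) stop("window longer than the record")
  nfft <- 2^ceiling(log2(window_s * rate))
  sp <- signal::specgram(channel, n = nfft, Fs = rate,
                         window = nfft, overlap = nfft / 2)
  pow <- Mod(sp$S)^2
  freq <- as.numeric(sp$f)
  tmid <- as.numeric(sp$t)
  rows <- freq >= band[1L] & freq <= band[2L]
  if (!any(rows)) stop("band outside the spectrogram frequency range")
  bp <- log10(colMeans(pow[rows, , drop = FALSE]) + 1e-300)

  med <- stats::median(bp)
  sc <- stats::mad(bp)
  z <- if (sc > 0) (bp - med) / sc else rep(0, length(bp))
  # movement must be broadband AND at least an order of magnitude above
  # the quiet floor; waveform harmonics of vigorous sniffing clear the
  # robust-z bar alone but not the absolute one
  hot <- if (sc > 0) (z > z_threshold) & (bp - med > 1.5) else rep(FALSE, length(bp))
  runs <- true_runs(hot)
  hop <- if (length(tmid) > 1L) tmid[2L] - tmid[1L] else window_s
  events <- if (nrow(runs)) {
    iv <- merge_intervals(tmid[runs$start] - hop / 2,
                          tmid[runs$end] + hop / 2, gap = 0.3)
    iv <- iv[iv$end - iv$start >= min_duration_s, , drop = FALSE]
    mag <- vapply(seq_len(nrow(iv)), function(i) {
      max(z[tmid >= iv$start[i] & tmid <= iv$end[i]])
    }, numeric(1))
    event_series("movement", pmax(iv$start, 0), iv$end - pmax(iv$start, 0), mag)
  } else {
    event_series("movement", numeric(0))
  }
  list(
    spectrogram = list(time = tmid, freq = freq, power = pow),
    band_power = data.frame(time = tmid, log_power = bp, z = z),
    events = events
  )
}
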