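#' Classification thresholds
#'
#' Central registry of the tunables of the response-class rule cascade.
#' Every qualitative phrase of the class definitions is pinned to an
#' explicit, testable number here.
#'
#' @param alpha_delta Two-sided significance level for calling an epoch
#'   change (Delta) non-zero against the circular-shift null.
#' @param alpha_onset Significance level of the onset-window elevation
#'   (excited-adapting rule).
#' @param onset_peak_z Excited-adapting rule: the onset-window peak must
#'   exceed this many robust SDs of the baseline dF/F -- an onset burst
#'   must tower over resting activity (these cells are silent or weakly
#'   active at rest).
#' @param alpha_sustained Significance level of the sustained elevation
#'   (excited-graded rule).
#' @param alpha_event Significance of the sign test on event leads
#'   (sniff/expiratory rules).
#' @param event_min_frac_pos Minimum fraction of matched events with a
#'   positive lead (sniff/expiratory rules).
#' @param event_max_iqr Maximum interquartile range of the matched leads,
#'   s: genuinely event-locked activity has a tight lead distribution,
#'   chance matches on a busy trace scatter across the whole window.
#' @param alpha_fr Significance of the breathing-frequency correlation
#'   (tonic exclusion and respiratory-related rule).
#' @param inhibited_ratio "Greatly reduced": epoch transient rate below
#'   this fraction of the baseline rate, in both hypercapnic epochs.
#' @param inhibited_min_rate Minimum baseline transient rate (events/s)
#'   for the inhibited rule ("spontaneous activity at rest").
#' @param adaptation_cutoff Adaptation index above which a response is
#'   adapting rather than graded.
#' @param onset_window_s Onset window at the start of the first
#'   hypercapnic epoch, s.
#' @param ea_min_onset_rate Excited-adapting rule: minimum transient rate
#'   inside the onset window, events/s (an adapting excitation is a burst
#'   of transients, not one isolated event).
#' @param tonic_min_rate "Active in all epochs": minimum per-epoch
#'   transient rate, events/s.
#' @param event_min_n,event_min_coverage Minimum matched behavioural
#'   events and matched fraction for the event-locked rules.
#' @param event_min_lead,event_max_lead Plausible lead window, s.
#' @param nc_rr_min_transients Minimum transient count for the
#'   respiratory-related rule (a correlation needs events to carry it).
#' @param recovery_ratio Graded rule: recovery-epoch elevation must drop
#'   below this fraction of the 6% elevation ("returned to baseline").
#' @param eps_factor,delta_factor Near-origin radius and identity-band
#'   half-width of the two-component plot, as multiples of the population
#'   robust SD of the Delta values (geometric fallback).
#' @param z_threshold Transient-detection threshold used throughout.
#' @param min_shift_s Shortest circular shift admitted into null
#'   distributions, s.
#' @return A list of class `classify_config`.
#' @export
classify_config <- function(alpha_delta = 0.01,
                            alpha_onset = 0.05,
                            onset_peak_z = 10,
                            alpha_sustained = 0.05,
                            alpha_event = 0.05,
                            alpha_fr = 0.01,
                            inhibited_ratio = 0.5,
                            inhibited_min_rate = 0.08,
                            adaptation_cutoff = 0.5,
                            onset_window_s = 60,
                            ea_min_onset_rate = 0.1,
                            tonic_min_rate = 0.06,
                            event_min_n = 5L,
                            event_min_coverage = 0.7,
                            event_min_lead = 0.05,
                            event_max_lead = 1.2,
                            event_min_frac_pos = 0.8,
                            event_max_iqr = 0.35,
                            nc_rr_min_transients = 25L,
                            recovery_ratio = 0.5,
                            eps_factor = 0.5,
                            delta_factor = 0.25,
                            z_threshold = 3,
                            min_shift_s = 30) {
  structure(as.list(environment()), class = "classify_config")
}

#' Protocol-aligned epoch statistics of one neuron
#'
#' Computes, on delay-corrected epochs and excluding movement-bout
#' frames: per-epoch mean dF/F and transient rate; the changes from
#' baseline at the lower and higher hypercapnic level (`delta_lo`,
#' `delta_hi`); the onset-window peak (rolling 10-s mean elevation within
#' the first `onset_window_s` of hypercapnia); late-hypercapnia activity
#' and the adaptation index `1 - late / onset_peak`; and recovery-epoch
#' activity.
#'
#' Two different nulls serve two different questions. The epoch deltas
#' are tested with a Welch t on 20-s sub-block means (`p_lo`, `p_hi`):
#' this asks whether the two epochs differ beyond the within-epoch
#' variability of the trace itself, and stays calibrated for unstructured
#' traces where a circular-shift null is anticonservative. The short
#' onset-window elevation is tested against the circular-shift null of
#' the whole trace (`onset_p`): for a window much shorter than the
#' record, the shift null asks exactly the right question -- could an
#' excursion this large arise at a random alignment.
#'
#' @param trace A [calcium_trace()] with `dff` computed.
#' @param protocol A [gas_protocol()] covering the trace.
#' @param movement Optional `event_series` of movement bouts; frames and
#'   transient onsets inside bouts are excluded. An epoch almost entirely
#'   covered by movement is flagged missing.
#' @param transients Optional precomputed `transient_table`.
#' @param config A [classify_config()].
#' @return Object of class `epoch_stats`.
#' @export
epoch_stats <- function(trace, protocol, movement = NULL, transients = NULL,
                        config = classify_config()) {
  stopifnot(inherits(trace, "calcium_trace"), inherits(protocol, "gas_protocol"))
  if (is.null(trace$dff)) stop("compute dF/F first")
  dff <- as.numeric(trace$dff)
  t <- frame_times(trace)
  n <- length(dff)
  rate <- trace$rate
  w <- epoch_windows(protocol)
  if (w$end[nrow(w)] > t[n] + max(1.5 / rate, 0.25) + 1e-6) {
    stop("protocol extends beyond the recording")
  }
  transients <- transients %||%
    detect_transients(trace, z_threshold = config$z_threshold)

  mv_on <- movement$onset %||% numeric(0)
  mv_end <- mv_on + (movement$duration %||% numeric(0))
  mask <- !in_intervals(t, mv_on, mv_end)
  ev_ok <- !in_intervals(transients$onset, mv_on, mv_end)

  idx_of <- function(tt) pmin(pmax(as.integer(round(tt * rate)) + 1L, 1L), n + 1L)
  mean_dff <- rates <- missing_ep <- numeric(nrow(w))
  for (i in seq_len(nrow(w))) {
    sel <- t >= w$start[i] & t < w$end[i] & mask
    live <- sum(t >= w$start[i] & t < w$end[i] & mask) / rate
    missing_ep[i] <- live < 0.05 * (w$end[i] - w$start[i])
    mean_dff[i] <- if (missing_ep[i]) NA_real_ else mean(dff[sel])
    k <- sum(ev_ok & transients$onset >= w$start[i] & transients$onset < w$end[i])
    rates[i] <- if (live > 0) k / live else NA_real_
  }

  hyper <- which(w$co2 > 0)
  lo_i <- if (length(hyper)) hyper[1L] else NA_integer_
  hi_i <- if (length(hyper) > 1L) hyper[2L] else NA_integer_
  rec_i <- if (length(hyper) && max(hyper) < nrow(w)) max(hyper) + 1L else NA_integer_

  a0 <- mean_dff[1L]
  delta_lo <- if (!is.na(lo_i)) mean_dff[lo_i] - a0 else NA_real_
  delta_hi <- if (!is.na(hi_i)) mean_dff[hi_i] - a0 else NA_real_

  # 20-s sub-block means per epoch, for Welch tests of the deltas
  block_means <- function(i) {
    edges <- seq(w$start[i], w$end[i], by = 20)
    if (edges[length(edges)] < w$end[i]) edges <- c(edges, w$end[i])
    out <- vapply(seq_len(length(edges) - 1L), function(b) {
      sel <- t >= edges[b] & t < edges[b + 1L] & mask
      if (sum(sel) < 0.5 * (edges[b + 1L] - edges[b]) * rate) return(NA_real_)
      mean(dff[sel])
    }, numeric(1))
    out[is.finite(out)]
  }
  bm0 <- block_means(1L)
  welch <- function(i) {
    if (is.na(i)) return(list(p = NA_real_, se = NA_real_))
    bm <- block_means(i)
    if (length(bm) < 3L || length(bm0) < 3L) {
      return(list(p = NA_real_, se = NA_real_))
    }
    tt <- tryCatch(stats::t.test(bm, bm0), error = function(e) NULL)
    if (is.null(tt)) return(list(p = NA_real_, se = NA_real_))
    list(p = tt$p.value,
         se = sqrt(stats::var(bm) / length(bm) + stats::var(bm0) / length(bm0)))
  }
  nl <- welch(lo_i)
  nh <- welch(hi_i)

  min_shift <- as.integer(config$min_shift_s * rate)
  base_win <- c(idx_of(w$start[1L]), idx_of(w$end[1L]))

  onset_peak <- onset_p <- late <- adaptation <- onset_rate <- NA_real_
  if (!is.na(lo_i)) {
    on_end <- min(w$start[lo_i] + config$onset_window_s, w$end[lo_i])
    onset_rate <- sum(ev_ok & transients$onset >= w$start[lo_i] &
                        transients$onset < on_end) / (on_end - w$start[lo_i])
    sel <- which(t >= w$start[lo_i] & t < on_end)
    if (length(sel) > 3L) {
      rm10 <- roll_mean(dff[sel] - a0, odd_k(10, rate, length(sel)))
      onset_peak <- max(rm10)
    }
    no <- shift_null(dff, list(c(idx_of(w$start[lo_i]), idx_of(on_end)),
                               base_win), c(1, -1), min_shift)
    onset_p <- no$p
    last_i <- max(hyper)
    late_start <- max(w$end[last_i] - 60, w$start[last_i])
    lsel <- t >= late_start & t < w$end[last_i] & mask
    late <- mean(dff[lsel]) - a0
    if (is.finite(onset_peak) && onset_peak > 0) {
      adaptation <- 1 - max(late, 0) / onset_peak
    }
  }
  recovery <- if (!is.na(rec_i)) mean_dff[rec_i] - a0 else NA_real_

  base_sel <- t >= w$start[1L] & t < w$end[1L] & mask
  structure(list(
    roi_id = trace$roi_id,
    epochs = data.frame(co2 = w$co2, start = w$start, end = w$end,
                        mean_dff = mean_dff, rate = rates,
                        missing = as.logical(missing_ep)),
    a0 = a0,
    delta_lo = delta_lo, delta_hi = delta_hi,
    p_lo = nl$p, p_hi = nh$p,
    se_lo = nl$se, se_hi = nh$se,
    onset_peak = onset_peak, onset_p = onset_p, onset_rate = onset_rate,
    late = late, adaptation_index = adaptation,
    recovery = recovery,
    base_rate = rates[1L], rates = rates,
    base_sd = robust_sd(dff[base_sel]),
    n_transients = sum(ev_ok),
    co2_levels = c(lo = if (!is.na(lo_i)) w$co2[lo_i] else NA_real_,
                   hi = if (!is.na(hi_i)) w$co2[hi_i] else NA_real_)
  ), class = "epoch_stats")
}

#' @export
print.epoch_stats <- function(x, ...) {
  cat(sprintf(
    "Epoch stats %s: Delta_lo %.3f (p=%.3g), Delta_hi %.3f (p=%.3g), AI %.2f\n",
    x$roi_id, x$delta_lo, x$p_lo, x$delta_hi, x$p_hi, x$adaptation_index
  ))
  invisible(x)
}
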