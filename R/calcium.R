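#' Calcium ROI trace container
#'
#' @param f Raw fluorescence per frame, a.u.
#' @param rate Frame rate, frames/s. The standard miniscope rig acquires
#'   at 10-20 frames/s; other rates are accepted with a warning unless
#'   `check_rate = FALSE`.
#' @param roi_id ROI identifier.
#' @param t0 Time of the first frame, s.
#' @param morphology_ok Logical metadata flag: the cell's features (soma,
#'   large processes) were clearly visible upstream. Consumed by QC
#'   criterion 1; morphology itself is assessed before trace extraction.
#' @param check_rate Warn when the frame rate is outside 10-20 frames/s.
#' @return Object of class `calcium_trace` with fields `f`, `rate`, `t0`,
#'   `roi_id`, `f0` (baseline fluorescence, `NA` until [compute_dff()]),
#'   `dff` (F/F0 series, `NULL` until computed) and provenance flags.
#' @export
calcium_trace <- function(f, rate, roi_id = "roi", t0 = 0,
                          morphology_ok = TRUE, check_rate = TRUE) {
  stopifnot(rate > 0, all(is.finite(f)))
  if (check_rate && (rate < 10 || rate > 20)) {
    warning("frame rate ", rate, " frames/s is outside the usual 10-20 range")
  }
  structure(
    list(f = as.numeric(f), rate = rate, t0 = t0, roi_id = roi_id,
         f0 = NA_real_, dff = NULL, morphology_ok = isTRUE(morphology_ok),
         background_subtracted = FALSE),
    class = "calcium_trace"
  )
}

#' @export
print.calcium_trace <- function(x, ...) {
  cat(sprintf(
    "Calcium trace %s: %.1f s at %g frames/s%s%s\n",
    x$roi_id, length(x$f) / x$rate, x$rate,
    if (!is.na(x$f0)) sprintf(", F0 = %.3g", x$f0) else "",
    if (x$background_subtracted) ", background-subtracted" else ""
  ))
  invisible(x)
}

frame_times <- function(trace) {
  trace$t0 + (seq_along(trace$f) - 1) / trace$rate
}

#' Compute the F/F0 representation
#'
#' Baseline fluorescence F0 is a low-percentile statistic of the raw
#' trace over the baseline (0% CO2) window, which is robust to transients
#' riding on it; dF/F is then `F / F0`. The representation is invariant
#' under multiplicative gain: scaling F leaves dF/F unchanged.
#'
#' @param trace A [calcium_trace()].
#' @param baseline_window `c(start, end)` of the baseline epoch, s.
#' @param probs Percentile used for F0 (default 0.10).
#' @return The trace with `f0` and `dff` filled in.
#' @export
compute_dff <- function(trace, baseline_window, probs = 0.10) {
  stopifnot(inherits(trace, "calcium_trace"))
  t <- frame_times(trace)
  sel <- t >= baseline_window[1L] & t < baseline_window[2L]
  if (!any(sel)) stop("baseline window lies outside the recording")
  f0 <- stats::quantile(trace$f[sel], probs, names = FALSE)
  if (!is.finite(f0) || f0 <= 0) {
    stop("baseline fluorescence F0 must be positive")
  }
  trace$f0 <- f0
  trace$dff <- trace$f / f0
  trace
}

#' Subtract a background (null-signal) ROI
#'
#' Movement artefacts that survive motion correction can be removed by
#' drawing an ROI over a fluorescent-cell-free landmark (e.g. a blood
#' vessel border) and subtracting that null signal from the cell's trace.
#' The background dF/F is scaled by a least-squares coefficient fitted
#' over non-event frames of the cell trace, so a shared additive artefact
#' cancels exactly in the noise-free case.
#'
#' @param roi The cell [calcium_trace()] with `dff` computed.
#' @param background The background [calcium_trace()] with `dff` computed,
#'   on the same frame grid.
#' @param event_z Frames whose robust z exceeds this are treated as signal
#'   and excluded from the scale fit.
#' @return The corrected trace (`dff` replaced; `background_subtracted`
#'   flag set).
#' @export
subtract_background <- function(roi, background, event_z = 2) {
  stopifnot(inherits(roi, "calcium_trace"),
            inherits(background, "calcium_trace"))
  if (length(roi$f) != length(background$f) ||
      abs(roi$rate - background$rate) > 1e-9) {
    stop("ROI and background traces are on different frame grids")
  }
  if (is.null(roi$dff) || is.null(background$dff)) {
    stop("compute dF/F on both traces first")
  }
  y <- roi$dff - stats::median(roi$dff)
  x <- background$dff - stats::median(background$dff)
  sigma <- noise_sd(roi$dff)
  quiet <- abs(y) <= event_z * max(sigma, 1e-12) | abs(x) > 2 * max(sigma, 1e-12)
  if (sum(quiet) < 10L || sum(x[quiet]^2) == 0) {
    scale <- 0
  } else {
    scale <- sum(x[quiet] * y[quiet]) / sum(x[quiet]^2)
  }
  roi$dff <- roi$dff - scale * x
  roi$background_subtracted <- TRUE
  attr(roi$dff, "background_scale") <- scale
  roi
}
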