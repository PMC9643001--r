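#' QC thresholds
#'
#' @param movement_frac Fraction of transient onsets inside movement bouts
#'   above which criterion 2 can fail (jointly with the association test).
#' @param movement_alpha Significance level of the Fisher association test
#'   between movement bouts and transient occurrence.
#' @param min_transients Minimum number of detected transients for
#'   criterion 3 (fluorescence changed relative to background).
#' @param drift_pct_per_min Maximum |linear trend| of the baseline
#'   envelope, percent of F0 per minute (criterion 4 proxy for a constant
#'   focal plane).
#' @param z_threshold Transient-detection threshold used inside QC.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(movement_frac = 0.5, movement_alpha = 0.01,
                      min_transients = 1L, drift_pct_per_min = 5,
                      z_threshold = 3) {
  structure(list(movement_frac = movement_frac,
                 movement_alpha = movement_alpha,
                 min_transients = min_transients,
                 drift_pct_per_min = drift_pct_per_min,
                 z_threshold = z_threshold), class = "qc_config")
}

#' Four-criterion cell quality control
#'
#' A trace is eligible for response classification only when all four
#' criteria pass:
#' \enumerate{
#'   \item cell features (soma, processes) clearly visible -- an upstream
#'     metadata flag on the trace, since morphology is judged on the
#'     movie, not the trace;
#'   \item signals occur in the absence of movement or are unaffected by
#'     it -- fails when the bulk of transient onsets fall inside movement
#'     bouts \emph{and} a Fisher test on the bout-by-transient
#'     contingency of 1-s time bins shows significant association;
#'   \item fluorescence changed relative to the background -- at least
#'     `min_transients` detected transients;
#'   \item the focal plane remained constant -- the linear trend of the
#'     lower (10th percentile per 30-s block) dF/F envelope stays below
#'     `drift_pct_per_min`.
#' }
#'
#' Verdicts are invariant under multiplicative gain of the raw
#' fluorescence because every statistic is computed on dF/F.
#'
#' @param trace A [calcium_trace()] with `dff` computed.
#' @param movement An `event_series` of movement bouts (may be empty).
#' @param transients Optional precomputed `transient_table`.
#' @param config A [qc_config()].
#' @return Object of class `qc_result`: `eligible`, logical `criteria`
#'   (length 4), `reasons` (character), `metrics`.
#' @export
qc_cell <- function(trace, movement, transients = NULL,
                    config = qc_config()) {
  stopifnot(inherits(trace, "calcium_trace"))
  if (is.null(trace$dff)) stop("compute dF/F first")
  transients <- transients %||%
    detect_transients(trace, z_threshold = config$z_threshold)
  t <- frame_times(trace)
  total <- length(trace$f) / trace$rate
  reasons <- character(0)

  c1 <- isTRUE(trace$morphology_ok)
  if (!c1) reasons <- c(reasons, "criterion 1: cell features not clearly visible")

  # pad bouts: a transient onset is marked at the last sub-threshold
  # frame and can precede the bout boundary by a fraction of a second
  mv_on <- (movement$onset %||% numeric(0)) - 0.3
  mv_end <- mv_on + (movement$duration %||% numeric(0)) + 0.6
  frac_in <- NA_real_
  fisher_p <- NA_real_
  c2 <- TRUE
  if (nrow(transients) > 0L && length(mv_on) > 0L) {
    inside <- in_intervals(transients$onset, mv_on, mv_end)
    frac_in <- mean(inside)
    bins <- seq(0, total, by = 1)
    bin_mv <- in_intervals(bins[-length(bins)] + 0.5, mv_on, mv_end)
    bin_tr <- tabulate(findInterval(transients$onset, bins),
                       nbins = length(bins) - 1L) > 0L
    tab <- table(factor(bin_mv, c(FALSE, TRUE)),
                 factor(bin_tr, c(FALSE, TRUE)))
    fisher_p <- stats::fisher.test(tab, alternative = "greater")$p.value
    c2 <- !(frac_in >= config$movement_frac &&
              fisher_p < config$movement_alpha)
  }
  if (!c2) reasons <- c(reasons, "criterion 2: transients locked to movement bouts")

  c3 <- nrow(transients) >= config$min_transients
  if (!c3) reasons <- c(reasons, "criterion 3: no fluorescence change above background")

  # lower envelope: per-block low percentile of dF/F, linear trend
  block <- 30
  edges <- seq(0, total, by = block)
  if (length(edges) < 3L) edges <- c(0, total / 2, total)
  mids <- (edges[-1L] + edges[-length(edges)]) / 2
  env <- vapply(seq_along(mids), function(i) {
    sel <- t >= edges[i] & t < edges[i + 1L]
    if (!any(sel)) return(NA_real_)
    stats::quantile(trace$dff[sel], 0.10, names = FALSE)
  }, numeric(1))
  ok <- is.finite(env)
  drift <- if (sum(ok) >= 2L) {
    abs(stats::coef(stats::lm(env[ok] ~ mids[ok]))[[2L]]) * 60 * 100
  } else 0
  c4 <- drift <= config$drift_pct_per_min
  if (!c4) {
    reasons <- c(reasons,
                 sprintf("criterion 4: baseline drift %.1f%%/min exceeds %g%%/min",
                         drift, config$drift_pct_per_min))
  }

  structure(list(
    eligible = c1 && c2 && c3 && c4,
    criteria = c(morphology = c1, movement = c2, signal = c3, focal = c4),
    reasons = reasons,
    metrics = list(n_transients = nrow(transients), movement_fraction = frac_in,
                   movement_fisher_p = fisher_p, drift_pct_per_min = drift)
  ), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("QC: %s (criteria: %s)\n",
              if (x$eligible) "eligible" else "EXCLUDED",
              paste(names(x$criteria)[!x$criteria], collapse = ", ")))
  for (r in x$reasons) cat(" -", r, "\n")
  invisible(x)
}
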