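#' Two-component response analysis
#'
#' Places a neuron in the plane of (change at the lower CO2 level, change
#' at the higher CO2 level) relative to the identity line x = y:
#' adapting responders answer the first step more than the second and
#' fall below the line, graded responders above it, inhibited neurons in
#' the negative quadrant, and non-responders near the origin.
#'
#' When called on an [epoch_stats()] object the region is decided
#' primarily by significance: a neuron is near-origin unless it is
#' responsive at all (either delta distinguishable from within-epoch
#' variability, or a significant onset-window excursion), which avoids
#' misplacing low-rate cells whose epoch means fluctuate by counting
#' statistics alone. The geometric near-origin radius `eps` and identity
#' band `delta` act as fallbacks for bare coordinate input.
#'
#' @param stats An [epoch_stats()] object, or a numeric vector
#'   `c(delta_lo, delta_hi)`.
#' @param eps Near-origin radius for coordinate input (same units as the
#'   deltas).
#' @param delta Identity-band half-width; differences within the band are
#'   resolved by sign.
#' @param alpha Significance level applied to the stored delta p-values.
#' @param alpha_onset Significance level applied to the onset-window
#'   p-value when judging responsiveness (defaults to `alpha`).
#' @return A list: `point` (the two deltas), `region` (one of
#'   `"above-identity"`, `"below-identity"`, `"near-origin"`,
#'   `"negative-quadrant"`), `in_band` (logical: inside the identity
#'   band), `significant` (length-2 logical, when available).
#' @export
two_component <- function(stats, eps = 0.25, delta = 0, alpha = 0.01,
                          alpha_onset = alpha) {
  if (inherits(stats, "epoch_stats")) {
    d <- c(stats$delta_lo, stats$delta_hi)
    if (anyNA(d)) stop("both epoch changes must be finite")
    sig <- c(isTRUE(stats$p_lo < alpha), isTRUE(stats$p_hi < alpha))
    onset_sig <- isTRUE(stats$onset_p < alpha_onset)
    region <- if (!any(sig) && !onset_sig) {
      "near-origin"
    } else if (all(d < 0)) {
      "negative-quadrant"
    } else if (d[2L] - d[1L] > delta) {
      "above-identity"
    } else {
      "below-identity"
    }
    return(list(point = d, region = region,
                in_band = abs(d[2L] - d[1L]) <= delta, significant = sig))
  }
  d <- as.numeric(stats)
  stopifnot(length(d) == 2L, all(is.finite(d)))
  region <- if (sqrt(sum(d^2)) < eps) {
    "near-origin"
  } else if (all(d < 0)) {
    "negative-quadrant"
  } else if (d[2L] - d[1L] > delta) {
    "above-identity"
  } else {
    "below-identity"
  }
  list(point = d, region = region, in_band = abs(d[2L] - d[1L]) <= delta,
       significant = c(NA, NA))
}
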