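#' Gas protocol of stepped CO2 epochs
#'
#' Describes the ordered CO2 epochs of a hypercapnia run as they appear on
#' the recorded gas-analyzer readout. Gas analyzers sample the chamber
#' inflow through a delay line, so the readout lags the true chamber gas by
#' a fixed interval (typically 15-20 s); [epoch_windows()] removes that lag
#' to recover the epochs actually experienced by the animal.
#'
#' @param levels Ordered CO2 percentages, one per epoch (e.g. `c(0, 3, 6, 0)`).
#'   The first epoch must be the 0% baseline.
#' @param durations Epoch durations in seconds (recycled if scalar).
#' @param analyzer_delay Readout delay of the gas analyzer in seconds.
#' @param t0 Recording time of the start of the first epoch (seconds).
#' @return An object of class `gas_protocol`: a data.frame with columns
#'   `co2`, `start`, `end` (recorded readout times, seconds, half-open
#'   intervals) and an `analyzer_delay` attribute.
#' @examples
#' p <- gas_protocol(c(0, 3, 6, 0), 180, analyzer_delay = 17.5)
#' epoch_windows(p)
#' @export
gas_protocol <- function(levels, durations, analyzer_delay = 0, t0 = 0) {
  stopifnot(length(levels) >= 1, all(is.finite(levels)), all(levels >= 0))
  if (length(durations) == 1L) durations <- rep(durations, length(levels))
  stopifnot(length(durations) == length(levels), all(durations > 0))
  if (levels[1L] != 0) {
    stop("the first epoch must be the 0% CO2 baseline")
  }
  if (analyzer_delay < 0) stop("analyzer_delay must be >= 0")
  ends <- t0 + cumsum(durations)
  starts <- c(t0, ends[-length(ends)])
  out <- data.frame(co2 = as.numeric(levels), start = starts, end = ends)
  attr(out, "analyzer_delay") <- as.numeric(analyzer_delay)
  class(out) <- c("gas_protocol", "data.frame")
  out
}

#' Delay-corrected epoch windows
#'
#' Shifts the interior epoch boundaries of a recorded protocol earlier by
#' the analyzer delay, recovering the half-open time windows of the true
#' chamber gas. The start of the first epoch and the end of the last are
#' recording boundaries and are left untouched.
#'
#' @param protocol A [gas_protocol()].
#' @return A data.frame with columns `co2`, `start`, `end` in corrected
#'   (true-gas) time.
#' @export
epoch_windows <- function(protocol) {
  stopifnot(inherits(protocol, "gas_protocol"))
  delay <- attr(protocol, "analyzer_delay") %||% 0
  n <- nrow(protocol)
  starts <- protocol$start
  ends <- protocol$end
  if (n > 1L) {
    interior <- pmax(starts[1L], protocol$start[-1L] - delay)
    starts <- c(starts[1L], interior)
    ends <- c(interior, ends[n])
  }
  data.frame(co2 = protocol$co2, start = starts, end = ends)
}

#' @export
print.gas_protocol <- function(x, ...) {
  delay <- attr(x, "analyzer_delay") %||% 0
  cat(sprintf(
    "Gas protocol: %d epochs, %.0f s total, analyzer delay %.1f s\n",
    nrow(x), x$end[nrow(x)] - x$start[1L], delay
  ))
  print(as.data.frame(x), ...)
  invisible(x)
}

# CO2 level at each (true, delay-corrected) time point.
co2_at <- function(protocol, t) {
  w <- epoch_windows(protocol)
  lev <- rep(NA_real_, length(t))
  for (i in seq_len(nrow(w))) {
    lev[t >= w$start[i] & t < w$end[i]] <- w$co2[i]
  }
  lev[t >= w$end[nrow(w)]] <- w$co2[nrow(w)]
  lev[t < w$start[1L]] <- w$co2[1L]
  lev
}

# Validate that epochs are contiguous and non-overlapping (used by readers).
validate_protocol <- function(epochs) {
  if (nrow(epochs) > 1L) {
    if (any(abs(epochs$start[-1L] - epochs$end[-nrow(epochs)]) > 1e-9)) {
      stop("protocol epochs must be contiguous and non-overlapping")
    }
  }
  if (any(epochs$end <= epochs$start)) stop("protocol epochs must have positive duration")
  invisible(TRUE)
}
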