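#' Calcium transient kernel
#'
#' Peak-normalized difference-of-exponentials kernel modelling a GCaMP
#' transient: fast rise, exponential fall. Zero for `t < 0`; peak value 1.
#'
#' @param t Times relative to event onset, s.
#' @param rise_tau,decay_tau Rise and decay time constants, s
#'   (`decay_tau > rise_tau > 0`).
#' @return Kernel values, same length as `t`.
#' @export
ca_kernel <- function(t, rise_tau, decay_tau) {
  stopifnot(decay_tau > rise_tau, rise_tau > 0)
  tstar <- log(decay_tau / rise_tau) / (1 / rise_tau - 1 / decay_tau)
  peak <- exp(-tstar / decay_tau) - exp(-tstar / rise_tau)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- (exp(-t[pos] / decay_tau) - exp(-t[pos] / rise_tau)) / peak
  out
}

# Superpose kernels for a set of event times/amplitudes on a frame grid.
events_to_dff <- function(times, amps, frame_times, rise_tau, decay_tau) {
  sig <- numeric(length(frame_times))
  if (length(times) == 0L) return(sig)
  dt <- frame_times[2L] - frame_times[1L]
  span <- 30 * decay_tau  # e^-30: kernel tail below 1e-13 of the peak
  for (i in seq_along(times)) {
    j0 <- max(1L, as.integer(ceiling((times[i] - frame_times[1L]) / dt)) + 1L)
    j1 <- min(length(frame_times),
              as.integer(floor((times[i] + span - frame_times[1L]) / dt)) + 1L)
    if (j1 < j0) next
    jj <- j0:j1
    sig[jj] <- sig[jj] + amps[i] * ca_kernel(frame_times[jj] - times[i],
                                             rise_tau, decay_tau)
  }
  sig
}

#' Simulate the fluorescence trace of one neuron
#'
#' Draws calcium event times from an inhomogeneous Poisson process whose
#' rate follows the class template (onset bursts, graded levels,
#' suppression, offset rebound), or places events deterministically ahead
#' of behavioural events for the sniff-coding and expiratory classes.
#' Events are convolved with the fast-rise/exponential-decay kernel and
#' embedded in a raw-fluorescence trace with shot-like noise and slow
#' optical drift.
#'
#' @param template A [neuron_template()].
#' @param behavior Output of [simulate_breathing()] covering the protocol.
#' @param config The [sim_config()] used for `behavior`.
#' @param roi_id ROI identifier string.
#' @param seed Integer seed for this neuron (default derives from the
#'   config master seed).
#' @param qc_defect One of `"none"`, `"morphology"`, `"movement"`,
#'   `"flat"`, `"drift"`: injects an uncorrectable defect that the
#'   four-criterion QC is expected to catch (all but `"none"`).
#' @return A list: `trace` ([calcium_trace()] with raw fluorescence),
#'   `events` (ground-truth event times, s), `label`, `qc_defect`.
#' @export
simulate_neuron <- function(template, behavior, config, roi_id = "roi_1",
                            seed = NULL, qc_defect = "none") {
  stopifnot(inherits(template, "neuron_template"),
            inherits(config, "sim_config"))
  qc_defect <- match.arg(qc_defect,
                         c("none", "morphology", "movement", "flat", "drift"))
  set.seed(seed %||% derive_seed(config$seed, 2L))

  ep <- behavior$truth$epochs
  total <- ep$end[nrow(ep)]
  nf <- as.integer(round(total * config$ca_rate))
  tf <- (seq_len(nf) - 1) / config$ca_rate
  rise <- template$kernel_rise_tau %||% config$kernel_rise_tau
  decay <- template$kernel_decay_tau %||% config$kernel_decay_tau

  hyper <- ep$co2 > 0
  first_on <- if (any(hyper)) ep$start[which(hyper)[1L]] else NA_real_
  last_hyper <- if (any(hyper)) max(which(hyper)) else NA_integer_
  offset_t <- if (!is.na(last_hyper) && last_hyper < nrow(ep)) {
    ep$start[last_hyper + 1L]
  } else NA_real_

  epoch_of <- function(t) pmin(pmax(findInterval(t, ep$start), 1L), nrow(ep))

  rate_fun <- switch(template$class_label,
    "E_A" = , "I" = function(t) {
      i <- epoch_of(t)
      r <- ifelse(ep$co2[i] > 0, template$hyper_rate, template$base_rate)
      if (!is.na(first_on) && template$onset_burst_rate > 0) {
        r <- r + ifelse(t >= first_on,
                        template$onset_burst_rate *
                          exp(-(t - first_on) / template$onset_burst_tau), 0)
      }
      if (!is.na(offset_t) && template$rebound_rate > 0) {
        r <- r + ifelse(t >= offset_t,
                        template$rebound_rate *
                          exp(-(t - offset_t) / template$rebound_tau), 0)
      }
      r
    },
    "E_G" = function(t) {
      i <- epoch_of(t)
      r <- template$base_rate + template$rate_per_co2 * ep$co2[i]
      if (!is.na(first_on) && template$onset_burst_rate > 0) {
        r <- r + ifelse(t >= first_on,
                        template$onset_burst_rate *
                          exp(-(t - first_on) / template$onset_burst_tau), 0)
      }
      r
    },
    "NC-RR" = function(t) {
      zz <- resample_to(behavior$truth$wander$time, behavior$truth$wander$z, t)
      template$base_rate * pmax(0, 1 + template$fr_gain * zz)
    },
    function(t) rep(template$base_rate, length(t))  # T, NC, Sn, Exp background
  )

  # inhomogeneous Poisson by thinning
  r_grid <- rate_fun(seq(0, total, by = 0.25))
  r_max <- max(r_grid, 1e-9) * 1.05
  m <- stats::rpois(1L, r_max * total)
  cand <- sort(stats::runif(m, 0, total))
  events <- cand[stats::runif(m) < rate_fun(cand) / r_max]

  # event-locked classes: one event ahead of each behavioural event
  if (template$class_label == "Sn") {
    sn <- behavior$truth$sniffs$onset
    if (length(sn)) {
      leads <- stats::runif(length(sn), template$event_lead[1L],
                            template$event_lead[2L])
      events <- sort(c(events, pmax(0, sn - leads)))
    }
  } else if (template$class_label == "Exp") {
    ex <- behavior$truth$expirations
    if (nrow(ex)) {
      mu <- template$event_lead[as.character(ex$co2)]
      if (anyNA(mu)) stop("Exp template has no lead for some CO2 level")
      leads <- pmax(0.05, stats::rnorm(nrow(ex), mu, template$event_lead_sd))
      events <- sort(c(events, pmax(0, ex$onset - leads)))
    }
  }

  if (qc_defect == "flat") {
    events <- numeric(0)
  } else if (qc_defect == "movement") {
    mv <- behavior$truth$movements
    events <- numeric(0)
    for (i in seq_len(nrow(mv))) {
      nk <- 1L + stats::rpois(1L, 1.5)
      events <- c(events, stats::runif(nk, mv$onset[i],
                                       pmin(mv$end[i], total - 1e-3)))
    }
    events <- sort(events)
  }

  amps <- if (length(events)) {
    sdlog <- sqrt(log(1 + config$amp_cv^2))
    stats::rlnorm(length(events), log(config$amp_mean) - sdlog^2 / 2, sdlog)
  } else numeric(0)

  sig <- events_to_dff(events, amps, tf, rise, decay)
  phase <- stats::runif(1L, 0, 2 * pi)
  drift <- config$drift_amp * sin(2 * pi * tf / config$drift_period + phase)
  if (qc_defect == "drift") drift <- drift + 0.10 * tf / 60  # 10% of F0 per min
  noise <- stats::rnorm(nf, 0, config$ca_noise)
  f <- config$f0 * (1 + sig + drift + noise)

  trace <- calcium_trace(f, rate = config$ca_rate, roi_id = roi_id,
                         morphology_ok = qc_defect != "morphology")
  list(trace = trace, events = events, label = template$class_label,
       qc_defect = qc_defect)
}

#' Simulate a labelled population with shared breathing
#'
#' Generates one plethysmography recording and a set of calcium traces
#' with the requested class composition, all aligned to the same protocol
#' and behavioural events. Per-neuron seeds derive deterministically from
#' the master seed, so a fixed config yields an identical dataset.
#'
#' @param composition Named integer vector of per-class neuron counts,
#'   e.g. `c("E_A" = 27, "E_G" = 4, I = 5, Sn = 3, T = 5, NC = 35,
#'   "NC-RR" = 19)`.
#' @param config A [sim_config()].
#' @param qc_defects Optional named counts of additional defective traces
#'   to append, e.g. `c(morphology = 13, movement = 13, flat = 12,
#'   drift = 12)`; these carry a class template (`NC` for
#'   morphology/movement/flat, `T` for drift) but are expected to fail QC.
#' @param templates Optional named list of [neuron_template()] overrides
#'   per class label.
#' @return Object of class `ca_dataset`: list with `wbp`,
#'   `movement_channel`, `protocol`, `traces` (list of [calcium_trace()]),
#'   `truth` (labels data.frame with `roi_id`, `class`, `qc_defect`;
#'   per-neuron `events`; behavioural ground truth), and `config`.
#' @export
simulate_population <- function(composition, config, qc_defects = NULL,
                                templates = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (length(composition) == 0L) stop("composition is empty")
  if (any(composition < 0)) stop("composition counts must be >= 0")
  bad <- setdiff(names(composition),
                 c("E_A", "E_G", "I", "T", "Sn", "Exp", "NC", "NC-RR"))
  if (length(bad)) stop("unknown class label: ", paste(bad, collapse = ", "))

  behavior <- simulate_breathing(config)

  labels <- rep(names(composition), times = composition)
  defect <- rep("none", length(labels))
  if (!is.null(qc_defects)) {
    map <- c(morphology = "NC", movement = "NC", flat = "NC", drift = "T")
    stopifnot(all(names(qc_defects) %in% names(map)))
    labels <- c(labels, unname(map[rep(names(qc_defects), times = qc_defects)]))
    defect <- c(defect, rep(names(qc_defects), times = qc_defects))
  }

  traces <- vector("list", length(labels))
  events <- vector("list", length(labels))
  ids <- sprintf("roi_%03d", seq_along(labels))
  for (j in seq_along(labels)) {
    tpl <- templates[[labels[j]]] %||% neuron_template(labels[j])
    sim <- simulate_neuron(tpl, behavior, config, roi_id = ids[j],
                           seed = derive_seed(config$seed, 100L + j),
                           qc_defect = defect[j])
    traces[[j]] <- sim$trace
    events[[j]] <- sim$events
  }
  names(events) <- ids

  out <- list(
    wbp = behavior$trace,
    movement_channel = behavior$movement_channel,
    protocol = behavior$protocol,
    traces = traces,
    truth = list(
      labels = data.frame(roi_id = ids, class = labels, qc_defect = defect,
                          stringsAsFactors = FALSE),
      events = events,
      behavior = behavior$truth
    ),
    config = config
  )
  class(out) <- "ca_dataset"
  out
}

#' @export
print.ca_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic dataset: %d ROI traces, %.0f s recording, CO2 %s%%\n",
    length(x$traces),
    length(x$wbp$samples) / x$wbp$rate,
    paste(x$protocol$co2, collapse = "/")
  ))
  print(table(x$truth$labels$class))
  invisible(x)
}
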