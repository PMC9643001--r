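#' Classify one neuron into the eight response classes
#'
#' Applies the rule cascade in priority order; the behavioural-event
#' classes outrank the CO2 classes because their evidence is time-locked
#' and specific, and earlier CO2 rules are stricter than later ones:
#' \enumerate{
#'   \item \strong{Exp} -- expiration-locked: enough matched events,
#'     consistent positive lead (calcium precedes the event);
#'   \item \strong{Sn} -- sniff-locked, same evidence on sniff bouts;
#'   \item \strong{I} -- spontaneously active at rest, transient rate
#'     greatly reduced (below `inhibited_ratio` of baseline) in both
#'     hypercapnic epochs;
#'   \item \strong{E_A} -- significant onset-window elevation, adaptation
#'     index above `adaptation_cutoff`, below the identity line of the
#'     two-component plot (offset rebound supports but is not required);
#'   \item \strong{E_G} -- graded: `delta_hi > delta_lo > 0`, both
#'     significant, above the identity line, recovery returning toward
#'     baseline;
#'   \item \strong{T} -- tonic: active in every epoch with no significant
#'     epoch modulation and no breathing-frequency correlation;
#'   \item \strong{NC-RR} -- significant correlation with breathing
#'     frequency without CO2 modulation;
#'   \item \strong{NC} otherwise.
#' }
#'
#' @param stats An [epoch_stats()] object.
#' @param sniff_evidence,exp_evidence [onset_latency()] results against
#'   sniff and expiration onsets (or `NULL` when no events were
#'   available).
#' @param fr_correlation A [ventilation_correlation()] result for fR (or
#'   `NULL`).
#' @param config A [classify_config()].
#' @return Object of class `neuron_class`: `label`, `stats`, `region`,
#'   `evidence`, and `trail` (a data.frame logging every rule evaluated).
#' @export
classify_neuron <- function(stats, sniff_evidence = NULL,
                            exp_evidence = NULL, fr_correlation = NULL,
                            config = classify_config()) {
  stopifnot(inherits(stats, "epoch_stats"))
  trail <- data.frame(rule = character(0), passed = logical(0),
                      detail = character(0), stringsAsFactors = FALSE)
  note <- function(rule, passed, detail) {
    trail <<- rbind(trail, data.frame(rule = rule, passed = passed,
                                      detail = detail,
                                      stringsAsFactors = FALSE))
    passed
  }
  finish <- function(label, region = NA_character_) {
    structure(list(label = label, stats = stats, region = region,
                   evidence = list(sniff = sniff_evidence,
                                   exp = exp_evidence,
                                   fr = fr_correlation),
                   trail = trail),
              class = "neuron_class")
  }

  if (any(stats$epochs$missing) || anyNA(c(stats$delta_lo, stats$delta_hi))) {
    note("missing-epochs", TRUE, "epoch unusable (movement or absent)")
    return(finish("unclassifiable"))
  }

  event_rule <- function(ev, name) {
    if (is.null(ev) || ev$n_matched < config$event_min_n) {
      return(note(name, FALSE, "too few matched events"))
    }
    ld <- ev$leads[is.finite(ev$leads)]
    frac_pos <- if (length(ld)) mean(ld > 0) else NA_real_
    iqr <- if (length(ld)) stats::IQR(ld) else NA_real_
    ok <- ev$coverage >= config$event_min_coverage &&
      is.finite(ev$median_lead) &&
      ev$median_lead >= config$event_min_lead &&
      ev$median_lead <= config$event_max_lead &&
      is.finite(frac_pos) && frac_pos >= config$event_min_frac_pos &&
      is.finite(iqr) && iqr <= config$event_max_iqr &&
      is.finite(ev$sign_p) && ev$sign_p < config$alpha_event
    note(name, ok, sprintf(
      "matched %d/%d, median lead %.2fs, %.0f%% positive, IQR %.2fs, sign p %.3g",
      ev$n_matched, ev$n_events, ev$median_lead, 100 * frac_pos, iqr,
      ev$sign_p))
  }

  if (event_rule(exp_evidence, "expiratory")) return(finish("Exp"))
  if (event_rule(sniff_evidence, "sniff")) return(finish("Sn"))

  r0 <- stats$base_rate
  r_lo <- stats$epochs$rate[which(stats$epochs$co2 > 0)[1L]]
  hyper <- which(stats$epochs$co2 > 0)
  r_hi <- if (length(hyper) > 1L) stats$epochs$rate[hyper[2L]] else r_lo
  inh <- is.finite(r0) && r0 >= config$inhibited_min_rate &&
    r_lo < config$inhibited_ratio * r0 && r_hi < config$inhibited_ratio * r0
  if (note("inhibited", inh,
           sprintf("rates %.3f -> %.3f/%.3f events/s", r0, r_lo, r_hi))) {
    tc <- two_component(stats, alpha = config$alpha_delta,
                        alpha_onset = config$alpha_onset)
    return(finish("I", tc$region))
  }

  tc <- two_component(stats, alpha = config$alpha_delta,
                      alpha_onset = config$alpha_onset)
  ea <- is.finite(stats$onset_p) && stats$onset_p < config$alpha_onset &&
    is.finite(stats$onset_peak) &&
    stats$onset_peak >= config$onset_peak_z * stats$base_sd &&
    is.finite(stats$onset_rate) &&
    stats$onset_rate >= config$ea_min_onset_rate &&
    is.finite(stats$adaptation_index) &&
    stats$adaptation_index > config$adaptation_cutoff &&
    is.finite(stats$delta_lo) && stats$delta_lo > 0 &&
    tc$region == "below-identity"
  if (note("excited-adapting", ea,
           sprintf("onset p %.3g, AI %.2f, region %s",
                   stats$onset_p, stats$adaptation_index, tc$region))) {
    return(finish("E_A", tc$region))
  }

  eg <- is.finite(stats$delta_lo) && stats$delta_lo > 0 &&
    stats$delta_hi > stats$delta_lo &&
    stats$p_lo < config$alpha_sustained &&
    stats$p_hi < config$alpha_sustained &&
    tc$region == "above-identity" &&
    (!is.finite(stats$recovery) ||
       stats$recovery < config$recovery_ratio * stats$delta_hi)
  if (note("excited-graded", eg,
           sprintf("deltas %.3f < %.3f, p %.3g/%.3g, recovery %.3f",
                   stats$delta_lo, stats$delta_hi, stats$p_lo, stats$p_hi,
                   stats$recovery))) {
    return(finish("E_G", tc$region))
  }

  fr_sig <- !is.null(fr_correlation) && is.finite(fr_correlation$p) &&
    fr_correlation$p < config$alpha_fr
  no_co2 <- stats$p_lo >= config$alpha_delta &&
    stats$p_hi >= config$alpha_delta

  tonic <- all(is.finite(stats$rates)) &&
    all(stats$rates >= config$tonic_min_rate) && no_co2 && !fr_sig
  if (note("tonic", tonic,
           sprintf("min rate %.3f events/s, fR corr %s",
                   suppressWarnings(min(stats$rates)),
                   if (fr_sig) "significant" else "ns"))) {
    return(finish("T", tc$region))
  }

  ncrr <- fr_sig && no_co2 &&
    stats$n_transients >= config$nc_rr_min_transients
  if (note("respiratory-related", ncrr,
           sprintf("fR r %.2f p %.3g, %d transients",
                   fr_correlation$r %||% NA_real_,
                   fr_correlation$p %||% NA_real_, stats$n_transients))) {
    return(finish("NC-RR", tc$region))
  }

  note("non-coding", TRUE, "no earlier rule matched")
  finish("NC", tc$region)
}

#' @export
print.neuron_class <- function(x, ...) {
  cat(sprintf("Neuron %s: %s (region %s)\n",
              x$stats$roi_id, x$label, x$region))
  invisible(x)
}

#' Classify a whole dataset
#'
#' Runs the full trace-level pipeline on a dataset: breath segmentation
#' and ventilation metrics from the WBP trace, sniff / active-expiration
#' / movement detection, per-ROI dF/F and four-criterion QC, epoch
#' statistics, event-locked evidence, and the rule cascade. Only
#' QC-eligible neurons are classified.
#'
#' @param dataset A `ca_dataset` (from [simulate_population()] or
#'   [read_dataset()]).
#' @param config A [classify_config()].
#' @param qc_cfg A [qc_config()].
#' @return Object of class `population_classification`: `table` (one row
#'   per trace: label, deltas, region, rates, evidence, QC verdict),
#'   `counts` (per-label counts over eligible neurons), `qc` (eligible /
#'   total and per-criterion failures), `modulated` (strict E_A+E_G+I
#'   count and the broader accounting that also counts sniff-coding
#'   cells), `events` (detected sniff/expiration/movement series) and
#'   `vent` (the ventilation series).
#' @export
classify_population <- function(dataset, config = classify_config(),
                                qc_cfg = qc_config()) {
  stopifnot(inherits(dataset, "ca_dataset"))
  protocol <- dataset$protocol
  w <- epoch_windows(protocol)
  baseline <- c(w$start[1L], w$end[1L])

  breaths <- detect_breaths(dataset$wbp)
  total_s <- length(dataset$wbp$samples) / dataset$wbp$rate
  vent <- compute_ventilation(breaths, end_time = total_s)
  movement <- movement_sonogram(dataset$wbp)$events
  sniffs <- detect_sniff_bouts(vent, movement = movement)
  # bridge ventilation metrics across movement bouts: breaths inside a
  # bout are artefactual and would dilute the fR correlation
  bridge <- function(v0, onset, duration, pad) {
    bad <- in_intervals(v0$time, onset - pad, onset + duration + pad)
    for (colv in c("vt", "fr")) {
      v <- v0[[colv]]
      v[bad] <- NA
      v0[[colv]] <- resample_to(v0$time, v, v0$time)
    }
    v0$ve <- v0$vt * v0$fr
    v0
  }
  if (nrow(movement)) {
    vent <- bridge(vent, movement$onset, movement$duration, 0.5)
  }
  # the respiratory-related correlation targets eupneic fR variability;
  # sniff bouts are a separate behaviour with their own class and their
  # fR spikes would only dilute it
  vent_corr <- if (nrow(sniffs)) {
    bridge(vent, sniffs$onset, sniffs$duration, 1)
  } else vent
  exps <- detect_active_expiration(dataset$wbp, breaths,
                                   baseline_window = baseline,
                                   movement = movement)

  labels <- character(length(dataset$traces))
  rows <- vector("list", length(dataset$traces))
  details <- vector("list", length(dataset$traces))
  crit_fail <- c(morphology = 0L, movement = 0L, signal = 0L, focal = 0L)

  for (j in seq_along(dataset$traces)) {
    tr <- compute_dff(dataset$traces[[j]], baseline)
    trans <- detect_transients(tr, z_threshold = config$z_threshold)
    qc <- qc_cell(tr, movement, transients = trans, config = qc_cfg)
    if (!qc$eligible) {
      crit_fail <- crit_fail + as.integer(!qc$criteria)
      labels[j] <- "excluded"
      rows[[j]] <- data.frame(
        roi_id = tr$roi_id, label = "excluded", eligible = FALSE,
        delta_lo = NA_real_, delta_hi = NA_real_, region = NA_character_,
        base_rate = NA_real_, adaptation_index = NA_real_,
        sniff_lead = NA_real_, exp_lead = NA_real_, fr_r = NA_real_,
        fr_p = NA_real_, stringsAsFactors = FALSE
      )
      details[[j]] <- qc
      next
    }
    st <- epoch_stats(tr, protocol, movement = movement, transients = trans,
                      config = config)
    sn_ev <- if (nrow(sniffs)) {
      onset_latency(tr, sniffs, onset_threshold = config$z_threshold,
                    transients = trans)
    }
    ex_ev <- if (nrow(exps)) {
      onset_latency(tr, exps, onset_threshold = config$z_threshold,
                    transients = trans)
    }
    fr <- ventilation_correlation(tr, vent_corr, "fR", detrend = "epoch",
                                  protocol = protocol)
    cls <- classify_neuron(st, sn_ev, ex_ev, fr, config)
    labels[j] <- cls$label
    rows[[j]] <- data.frame(
      roi_id = tr$roi_id, label = cls$label, eligible = TRUE,
      delta_lo = st$delta_lo, delta_hi = st$delta_hi,
      region = cls$region %||% NA_character_,
      base_rate = st$base_rate, adaptation_index = st$adaptation_index,
      sniff_lead = if (!is.null(sn_ev)) sn_ev$median_lead else NA_real_,
      exp_lead = if (!is.null(ex_ev)) ex_ev$median_lead else NA_real_,
      fr_r = fr$r %||% NA_real_, fr_p = fr$p %||% NA_real_,
      stringsAsFactors = FALSE
    )
    details[[j]] <- cls
  }

  table <- do.call(rbind, rows)
  if (is.null(table)) {
    table <- data.frame(roi_id = character(0), label = character(0),
                        eligible = logical(0))
  }
  lv <- c("E_A", "E_G", "I", "T", "Sn", "Exp", "NC", "NC-RR",
          "unclassifiable")
  eligible <- table$label[table$eligible %in% TRUE]
  counts <- table(factor(eligible, levels = lv))
  strict <- sum(counts[c("E_A", "E_G", "I")])
  structure(list(
    table = table,
    counts = counts,
    qc = list(total = length(dataset$traces),
              eligible = sum(table$eligible %in% TRUE),
              criterion_failures = crit_fail),
    modulated = list(
      strict = as.integer(strict),
      with_sniff = as.integer(strict + counts[["Sn"]]),
      fraction_strict = as.numeric(strict) / max(1, length(eligible)),
      fraction_with_sniff =
        (as.numeric(strict) + counts[["Sn"]]) / max(1, length(eligible))
    ),
    events = list(sniffs = sniffs, expirations = exps, movement = movement),
    vent = vent,
    details = details,
    config = config
  ), class = "population_classification")
}

#' @export
print.population_classification <- function(x, ...) {
  cat(sprintf("Population classification: %d/%d eligible\n",
              x$qc$eligible, x$qc$total))
  print(x$counts)
  cat(sprintf("CO2-modulated: %d strict (E_A+E_G+I), %d incl. sniff-coding\n",
              x$modulated$strict, x$modulated$with_sniff))
  invisible(x)
}

#' Two-component scatter of a classified population
#'
#' Plots each eligible neuron at (change at lower CO2, change at higher
#' CO2), coloured by label, with the identity line.
#'
#' @param x A `population_classification`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.population_classification <- function(x, ...) {
  tab <- x$table[x$table$eligible %in% TRUE, , drop = FALSE]
  if (!nrow(tab)) {
    warning("nothing to plot")
    return(invisible(NULL))
  }
  cols <- c("E_A" = "#C2417F", "E_G" = "#2C7FB8", I = "#3949ab",
            T = "#7B5BB5", Sn = "#5E355E", Exp = "#7B3F00",
            NC = "#4CAF50", "NC-RR" = "#2E7D32",
            unclassifiable = "grey60")
  graphics::plot(tab$delta_lo, tab$delta_hi,
                 col = cols[tab$label], pch = 19,
                 xlab = "Delta dF/F at lower CO2",
                 ylab = "Delta dF/F at higher CO2", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::abline(h = 0, v = 0, col = "grey80")
  graphics::legend("topleft", legend = names(cols), col = cols, pch = 19,
                   cex = 0.7, bty = "n")
  invisible(x)
}
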