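#' Simulation configuration
#'
#' Bundles every tunable of the synthetic recording generator. Defaults
#' reproduce the standard awake hypercapnia paradigm: 3-min baseline, two
#' 3-min hypercapnic steps, 3-min recovery, whole-body plethysmography
#' (WBP) at 200 samples/s, single-photon calcium imaging at 15 frames/s,
#' and a gas analyzer readout delay of 17.5 s.
#'
#' Breathing rises stepwise with CO2 and partially adapts within each
#' epoch: on every step both respiratory frequency (fR) and tidal volume
#' (V_T) overshoot their sustained level by `overshoot` and relax with time
#' constant `adapt_tau`. Sniff bouts (brief high-fR, low-V_T runs), active
#' expirations (enlarged expiratory troughs during hypercapnia) and
#' movement bouts (broadband artefact excursions) are injected at known
#' times and reported as ground truth.
#'
#' @param protocol_levels Ordered CO2 percentages per epoch; first must be 0.
#' @param epoch_durations Seconds per epoch (recycled if scalar).
#' @param wbp_rate WBP sample rate, samples/s.
#' @param ca_rate Imaging frame rate, frames/s (10-20 in the standard rig).
#' @param seed Master seed; a fixed seed gives byte-identical datasets.
#' @param wbp_noise WBP white-noise SD as a fraction of the baseline
#'   inspiratory amplitude.
#' @param ca_noise Fluorescence noise SD in dF/F0 units.
#' @param movement_rate Movement bouts per minute.
#' @param movement_duration Movement bout duration, s.
#' @param movement_amp Movement artefact amplitude, multiples of the
#'   baseline inspiratory amplitude.
#' @param analyzer_delay Gas analyzer readout delay, s (typically 15-20).
#' @param body_mass Animal mass, g.
#' @param calibration mL of volume per WBP signal unit.
#' @param base_fr Eupneic respiratory frequency at 0% CO2, breaths/min.
#' @param base_vt_per_g Eupneic tidal volume, mL per g body mass.
#' @param fr_mult,vt_mult Named vectors mapping CO2 level (as character) to
#'   the sustained multiplier of fR and V_T.
#' @param overshoot Multiplicative overshoot applied to fR and V_T at each
#'   CO2 step before adaptation.
#' @param adapt_tau Within-epoch adaptation time constant, s.
#' @param fr_wander_sd SD of the slow eupneic fR wander (fraction of fR).
#' @param fr_wander_smooth_s Gaussian smoothing SD of the wander, s.
#' @param breath_dur_cv,breath_amp_cv Per-breath jitter CVs.
#' @param exp_depth Passive expiratory trough depth as a fraction of the
#'   inspiratory peak.
#' @param exp_depth_cv Per-breath jitter CV of the trough depth ratio.
#' @param exp_trough_factor Trough-depth multiplier of an active expiration.
#' @param exp_rate_per_co2 Active expirations per minute per % CO2 (only in
#'   hypercapnic epochs).
#' @param sniff_rate Sniff bouts per minute.
#' @param sniff_duration Sniff bout duration, s.
#' @param sniff_fr_factor,sniff_vt_factor fR and V_T multipliers during a
#'   sniff bout.
#' @param sniff_fr_cap Physiological ceiling on sniffing frequency,
#'   breaths/min (~12 Hz in mouse).
#' @param f0 Baseline fluorescence, a.u.
#' @param indicator `"GCaMP6s"` (slow) or `"GCaMP6f"` (fast); sets the
#'   default transient decay time constant.
#' @param kernel_rise_tau,kernel_decay_tau Transient kernel time constants,
#'   s; `NULL` takes the indicator default (rise 0.2 s; decay 1.5 s for 6s,
#'   0.7 s for 6f).
#' @param amp_mean,amp_cv Mean and CV of per-event dF/F0 amplitudes
#'   (lognormal).
#' @param drift_amp,drift_period Amplitude (dF/F0) and period (s) of the
#'   slow optical drift.
#' @return Object of class `sim_config` (a validated list).
#' @seealso [simulate_breathing()], [simulate_population()]
#' @export
sim_config <- function(protocol_levels = c(0, 3, 6, 0),
                       epoch_durations = 180,
                       wbp_rate = 200,
                       ca_rate = 15,
                       seed = 1L,
                       wbp_noise = 0.05,
                       ca_noise = 0.05,
                       movement_rate = 0.5,
                       movement_duration = 2,
                       movement_amp = 6,
                       analyzer_delay = 17.5,
                       body_mass = 25,
                       calibration = 1,
                       base_fr = 180,
                       base_vt_per_g = 0.0064,
                       fr_mult = c("0" = 1, "3" = 1.35, "6" = 1.7, "9" = 2.0),
                       vt_mult = c("0" = 1, "3" = 1.5, "6" = 2.0, "9" = 2.4),
                       overshoot = 1.15,
                       adapt_tau = 30,
                       fr_wander_sd = 0.08,
                       fr_wander_smooth_s = 6,
                       breath_dur_cv = 0.06,
                       breath_amp_cv = 0.08,
                       exp_depth = 0.25,
                       exp_depth_cv = 0.10,
                       exp_trough_factor = 5,
                       exp_rate_per_co2 = 0.4,
                       sniff_rate = 1,
                       sniff_duration = 2,
                       sniff_fr_factor = 3,
                       sniff_vt_factor = 0.5,
                       sniff_fr_cap = 720,
                       f0 = 100,
                       indicator = c("GCaMP6s", "GCaMP6f"),
                       kernel_rise_tau = NULL,
                       kernel_decay_tau = NULL,
                       amp_mean = 1,
                       amp_cv = 0.2,
                       drift_amp = 0.02,
                       drift_period = 300) {
  indicator <- match.arg(indicator)
  if (length(epoch_durations) == 1L) {
    epoch_durations <- rep(epoch_durations, length(protocol_levels))
  }
  cfg <- list(
    protocol_levels = as.numeric(protocol_levels),
    epoch_durations = as.numeric(epoch_durations),
    wbp_rate = wbp_rate, ca_rate = ca_rate, seed = as.integer(seed),
    wbp_noise = wbp_noise, ca_noise = ca_noise,
    movement_rate = movement_rate, movement_duration = movement_duration,
    movement_amp = movement_amp,
    analyzer_delay = analyzer_delay,
    body_mass = body_mass, calibration = calibration,
    base_fr = base_fr, base_vt_per_g = base_vt_per_g,
    fr_mult = fr_mult, vt_mult = vt_mult,
    overshoot = overshoot, adapt_tau = adapt_tau,
    fr_wander_sd = fr_wander_sd, fr_wander_smooth_s = fr_wander_smooth_s,
    breath_dur_cv = breath_dur_cv, breath_amp_cv = breath_amp_cv,
    exp_depth = exp_depth, exp_depth_cv = exp_depth_cv,
    exp_trough_factor = exp_trough_factor,
    exp_rate_per_co2 = exp_rate_per_co2,
    sniff_rate = sniff_rate, sniff_duration = sniff_duration,
    sniff_fr_factor = sniff_fr_factor, sniff_vt_factor = sniff_vt_factor,
    sniff_fr_cap = sniff_fr_cap,
    f0 = f0, indicator = indicator,
    kernel_rise_tau = kernel_rise_tau %||% 0.2,
    kernel_decay_tau = kernel_decay_tau %||%
      if (indicator == "GCaMP6f") 0.7 else 1.5,
    amp_mean = amp_mean, amp_cv = amp_cv,
    drift_amp = drift_amp, drift_period = drift_period
  )
  stopifnot(
    cfg$wbp_rate > 0, cfg$ca_rate > 0,
    all(cfg$epoch_durations > 0),
    length(cfg$epoch_durations) == length(cfg$protocol_levels),
    cfg$protocol_levels[1L] == 0,
    cfg$kernel_decay_tau > cfg$kernel_rise_tau,
    cfg$kernel_rise_tau > 0,
    cfg$analyzer_delay >= 0, cfg$body_mass > 0, cfg$calibration > 0
  )
  for (lv in unique(cfg$protocol_levels)) {
    key <- as.character(lv)
    if (!key %in% names(cfg$fr_mult) || !key %in% names(cfg$vt_mult)) {
      stop("no fR/V_T multiplier configured for CO2 level ", key)
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulation config: CO2 %s%% (%s s), WBP %g Hz, Ca %g fps, seed %d\n",
    paste(x$protocol_levels, collapse = "/"),
    paste(x$epoch_durations, collapse = "/"),
    x$wbp_rate, x$ca_rate, x$seed
  ))
  invisible(x)
}

# True (chamber-gas) epoch schedule implied by a config: starts at 0.
true_epochs <- function(config) {
  ends <- cumsum(config$epoch_durations)
  data.frame(
    co2 = config$protocol_levels,
    start = c(0, ends[-length(ends)]),
    end = ends
  )
}

# Recorded protocol: interior boundaries lag the true gas by the analyzer
# delay (the readout samples the chamber inflow through a delay line).
recorded_protocol <- function(config) {
  ep <- true_epochs(config)
  durations <- ep$end - ep$start
  p <- gas_protocol(ep$co2, durations, analyzer_delay = config$analyzer_delay)
  if (nrow(p) > 1L) {
    interior <- ep$start[-1L] + config$analyzer_delay
    p$start <- c(0, interior)
    p$end <- c(interior, ep$end[nrow(ep)])
  }
  p
}

#' Response-class template for the neuron generator
#'
#' Defines the firing-rate program of one of the eight response classes:
#' excited-adapting (`E_A`), excited-graded (`E_G`), inhibited (`I`), tonic
#' (`T`), sniff-coding (`Sn`), expiratory (`Exp`), non-coding (`NC`) and
#' non-coding respiratory-related (`NC-RR`). Calcium events are drawn from
#' an inhomogeneous Poisson process following the template (or placed
#' deterministically ahead of behavioural events for `Sn`/`Exp`) and
#' convolved with a fast-rise / exponential-decay kernel.
#'
#' @param class_label One of `"E_A"`, `"E_G"`, `"I"`, `"T"`, `"Sn"`,
#'   `"Exp"`, `"NC"`, `"NC-RR"`.
#' @param base_rate Baseline event rate, events/s.
#' @param hyper_rate Sustained event rate during hypercapnia (E_A, I), or
#'   `NULL` where not applicable.
#' @param rate_per_co2 Rate gain per % CO2 (E_G), events/s per %.
#' @param onset_burst_rate,onset_burst_tau Peak rate (events/s) and decay
#'   time constant (s) of the burst at the first CO2 step.
#' @param rebound_rate,rebound_tau Rebound burst at stimulus offset.
#' @param adaptation_tau Alias inspected by callers; equals
#'   `onset_burst_tau` for E_A.
#' @param event_lead Lead of calcium events before behavioural events, s.
#'   For `Sn` a length-2 range sampled uniformly per event; for `Exp` a
#'   named vector by CO2 level (positive: activity precedes the event).
#' @param event_lead_sd Per-event SD of the Exp lead, s.
#' @param fr_gain Gain of the NC-RR rate on the standardized slow fR
#'   wander.
#' @param kernel_rise_tau,kernel_decay_tau Kernel overrides, s (default:
#'   take from the simulation config).
#' @return Object of class `neuron_template`.
#' @export
neuron_template <- function(class_label,
                            base_rate = NULL,
                            hyper_rate = NULL,
                            rate_per_co2 = NULL,
                            onset_burst_rate = 0,
                            onset_burst_tau = 15,
                            rebound_rate = 0,
                            rebound_tau = 15,
                            adaptation_tau = NULL,
                            event_lead = NULL,
                            event_lead_sd = 0.05,
                            fr_gain = NULL,
                            kernel_rise_tau = NULL,
                            kernel_decay_tau = NULL) {
  classes <- c("E_A", "E_G", "I", "T", "Sn", "Exp", "NC", "NC-RR")
  if (!class_label %in% classes) {
    stop("unknown class label: ", class_label)
  }
  defaults <- switch(class_label,
    "E_A" = list(base_rate = 0.02, hyper_rate = 0.05,
                 onset_burst_rate = 0.8, onset_burst_tau = 20,
                 rebound_rate = 0.4, rebound_tau = 15),
    "E_G" = list(base_rate = 0.02, rate_per_co2 = 0.08,
                 onset_burst_rate = 0.3, onset_burst_tau = 8),
    "I"   = list(base_rate = 0.3, hyper_rate = 0.03,
                 rebound_rate = 0.45, rebound_tau = 15),
    "T"   = list(base_rate = 0.15),
    "Sn"  = list(base_rate = 0.005, event_lead = c(0.4, 0.8)),
    "Exp" = list(base_rate = 0.005,
                 event_lead = c("3" = 0.6, "6" = 0.5, "9" = 0.3)),
    "NC"  = list(base_rate = 0.02),
    "NC-RR" = list(base_rate = 0.15, fr_gain = 2.5)
  )
  tpl <- list(
    class_label = class_label,
    base_rate = base_rate %||% defaults$base_rate %||% 0,
    hyper_rate = hyper_rate %||% defaults$hyper_rate,
    rate_per_co2 = rate_per_co2 %||% defaults$rate_per_co2,
    onset_burst_rate = if (missing(onset_burst_rate))
      defaults$onset_burst_rate %||% 0 else onset_burst_rate,
    onset_burst_tau = if (missing(onset_burst_tau))
      defaults$onset_burst_tau %||% 15 else onset_burst_tau,
    rebound_rate = if (missing(rebound_rate))
      defaults$rebound_rate %||% 0 else rebound_rate,
    rebound_tau = if (missing(rebound_tau))
      defaults$rebound_tau %||% 15 else rebound_tau,
    event_lead = event_lead %||% defaults$event_lead,
    event_lead_sd = event_lead_sd,
    fr_gain = fr_gain %||% defaults$fr_gain,
    kernel_rise_tau = kernel_rise_tau,
    kernel_decay_tau = kernel_decay_tau
  )
  tpl$adaptation_tau <- adaptation_tau %||% tpl$onset_burst_tau
  stopifnot(
    tpl$base_rate >= 0,
    is.null(tpl$hyper_rate) || tpl$hyper_rate >= 0,
    tpl$onset_burst_rate >= 0, tpl$rebound_rate >= 0
  )
  if (class_label == "Exp" && any(tpl$event_lead <= 0)) {
    stop("Exp event_lead must be positive: activity precedes the event")
  }
  if (class_label == "Sn" &&
      (length(tpl$event_lead) != 2L || any(tpl$event_lead < 0))) {
    stop("Sn event_lead must be a non-negative range c(lo, hi)")
  }
  class(tpl) <- "neuron_template"
  tpl
}

#' @export
print.neuron_template <- function(x, ...) {
  cat(sprintf("Neuron template: class %s, base rate %.3g events/s\n",
              x$class_label, x$base_rate))
  invisible(x)
}
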