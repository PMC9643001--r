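#' Simulate a whole-body plethysmography recording
#'
#' Builds a pressure trace breath by breath. Each breath is one
#' asymmetric sinusoid cycle (inspiration 35% of the cycle, expiration
#' 65%) whose inspiratory peak encodes tidal volume and whose expiratory
#' trough is a fixed fraction of the peak during eupnea. Respiratory
#' frequency and tidal volume follow the CO2 protocol with per-step
#' overshoot and within-epoch adaptation, plus a slow smooth wander of fR.
#' Sniff bouts, active expirations and movement-artefact bouts are
#' injected at known times and returned as ground truth.
#'
#' @param config A [sim_config()].
#' @return A list with elements:
#' \describe{
#'   \item{trace}{[pleth_trace()] pressure recording.}
#'   \item{movement_channel}{Numeric vector: the external movement channel
#'     (same sample rate), quiet except during movement bouts.}
#'   \item{protocol}{The recorded [gas_protocol()] (analyzer-delayed).}
#'   \item{truth}{List of ground truth: `breaths` (per-breath onset, peak,
#'     trough, V_T, duration, flags), `sniffs`, `expirations`, `movements`
#'     (data.frames with `onset`/`end`), `epochs` (true gas schedule),
#'     `wander` (1-Hz grid of the standardized slow fR wander), and the
#'     per-epoch target fR/V_T trajectories at 1 Hz.}
#' }
#' @export
simulate_breathing <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))

  ep <- true_epochs(config)
  total <- ep$end[nrow(ep)]
  rate <- config$wbp_rate
  n <- as.integer(round(total * rate))

  # epoch feasibility: at least 10 breaths at the sustained target fR
  fr_sus <- config$base_fr * unname(config$fr_mult[as.character(ep$co2)])
  if (any((ep$end - ep$start) * fr_sus / 60 < 10)) {
    stop("epoch shorter than 10 breaths at its target fR")
  }

  # slow fR wander: smoothed standardized noise on a 1 Hz grid
  tg <- seq(0, total, by = 1)
  z <- stats::rnorm(length(tg))
  sm <- config$fr_wander_smooth_s
  kern <- stats::dnorm(seq(-3 * sm, 3 * sm, by = 1), sd = sm)
  kern <- kern / sum(kern)
  zc <- c(rev(z[seq_len(3 * sm)]), z, rev(z[length(z) - seq_len(3 * sm) + 1L]))
  zs <- as.numeric(stats::filter(zc, kern, sides = 2L))
  zs <- zs[(3 * sm + 1L):(3 * sm + length(z))]
  # high-pass: eupneic variability, not a slow drift -- remove the 60-s
  # running mean so epoch- and onset-window averages stay centred
  zs <- zs - roll_mean(zs, 61L)
  zs <- (zs - mean(zs)) / stats::sd(zs)
  wander_at <- function(t) resample_to(tg, zs, t)

  draw_times <- function(rate_per_s, lo, hi, min_sep, avoid = numeric(0),
                         avoid_pad = 0) {
    span <- hi - lo
    if (span <= 0 || rate_per_s <= 0) return(numeric(0))
    m <- stats::rpois(1L, rate_per_s * span)
    if (m == 0L) return(numeric(0))
    cand <- sort(stats::runif(m, lo, hi))
    kept <- numeric(0)
    last <- -Inf
    for (tt in cand) {
      if (tt - last < min_sep) next
      if (length(avoid) && any(abs(tt - avoid) < avoid_pad)) next
      kept <- c(kept, tt)
      last <- tt
    }
    kept
  }

  boundaries <- c(ep$start, ep$end[nrow(ep)])

  sniff_onsets <- draw_times(config$sniff_rate / 60, 10, total - 10,
                             config$sniff_duration + 6,
                             avoid = boundaries, avoid_pad = 6)

  exp_times <- numeric(0)
  exp_co2 <- numeric(0)
  for (i in seq_len(nrow(ep))) {
    if (ep$co2[i] <= 0) next
    tt <- draw_times(config$exp_rate_per_co2 * ep$co2[i] / 60,
                     ep$start[i] + 5, ep$end[i] - 2, 4,
                     avoid = sniff_onsets + config$sniff_duration / 2,
                     avoid_pad = config$sniff_duration / 2 + 2)
    exp_times <- c(exp_times, tt)
    exp_co2 <- c(exp_co2, rep(ep$co2[i], length(tt)))
  }

  mov_onsets <- draw_times(config$movement_rate / 60, 10, total - 10, 10,
                           avoid = c(sniff_onsets, exp_times), avoid_pad = 4)

  base_vt_signal <- config$base_vt_per_g * config$body_mass / config$calibration
  a_base <- base_vt_signal / (1 + config$exp_depth)

  # sustained multipliers and step-start values per epoch
  fr_m <- unname(config$fr_mult[as.character(ep$co2)])
  vt_m <- unname(config$vt_mult[as.character(ep$co2)])
  start_fac <- function(m) {
    prev <- c(m[1L], m[-length(m)])
    ifelse(m > prev, config$overshoot * m, prev)
  }
  fr_start <- start_fac(fr_m)
  vt_start <- start_fac(vt_m)

  mult_at <- function(t, sus, st) {
    i <- findInterval(t, ep$start, left.open = FALSE)
    i <- pmin(pmax(i, 1L), nrow(ep))
    el <- t - ep$start[i]
    sus[i] + (st[i] - sus[i]) * exp(-el / config$adapt_tau)
  }

  pressure <- numeric(n)
  cap <- as.integer(total * config$base_fr *
                      max(config$fr_mult) * config$sniff_fr_factor / 60) + 50L
  b_onset <- b_dur <- b_peak_t <- b_peak_v <- b_trough_t <- b_trough_v <-
    b_vt <- numeric(cap)
  b_sniff <- b_exp <- logical(cap)
  exp_truth_onset <- rep(NA_real_, length(exp_times))
  exp_used <- logical(length(exp_times))

  t <- 0
  k <- 0L
  while (t < total - 1e-9) {
    in_sniff <- length(sniff_onsets) &&
      any(t >= sniff_onsets & t < sniff_onsets + config$sniff_duration)
    fr <- config$base_fr * mult_at(t, fr_m, fr_start) *
      (1 + config$fr_wander_sd * wander_at(t))
    vt <- base_vt_signal * mult_at(t, vt_m, vt_start)
    if (in_sniff) {
      fr <- min(fr * config$sniff_fr_factor, config$sniff_fr_cap)
      vt <- vt * config$sniff_vt_factor
    }
    dur <- 60 / fr * max(0.6, 1 + stats::rnorm(1L, 0, config$breath_dur_cv))
    vt_b <- vt * max(0.3, 1 + stats::rnorm(1L, 0, config$breath_amp_cv))

    depth_ratio <- config$exp_depth *
      max(0.4, 1 + stats::rnorm(1L, 0, config$exp_depth_cv))
    hit <- which(!exp_used & exp_times >= t & exp_times < t + dur)
    is_exp <- length(hit) > 0L
    if (is_exp) {
      depth_ratio <- depth_ratio * config$exp_trough_factor
      exp_used[hit[1L]] <- TRUE
    }
    a <- vt_b / (1 + config$exp_depth)  # inspiratory amplitude
    d <- depth_ratio * a                # trough depth

    ti <- 0.35 * dur
    te <- dur - ti
    i0 <- as.integer(floor(t * rate)) + 1L
    i1 <- min(n, as.integer(floor((t + dur) * rate)))
    if (i1 >= i0) {
      tt <- ((i0:i1) - 1) / rate - t
      insp <- tt < ti
      seg <- numeric(length(tt))
      seg[insp] <- a * sin(pi * tt[insp] / ti)
      seg[!insp] <- -d * sin(pi * (tt[!insp] - ti) / te)
      pressure[i0:i1] <- pressure[i0:i1] + seg
    }
    if (is_exp) exp_truth_onset[hit[1L]] <- t + ti

    k <- k + 1L
    b_onset[k] <- t
    b_dur[k] <- dur
    b_peak_t[k] <- t + ti / 2
    b_peak_v[k] <- a
    b_trough_t[k] <- t + ti + te / 2
    b_trough_v[k] <- -d
    b_vt[k] <- a + d
    b_sniff[k] <- in_sniff
    b_exp[k] <- is_exp
    t <- t + dur
  }
  idx <- seq_len(k)
  breaths <- data.frame(
    onset = b_onset[idx], duration = b_dur[idx],
    peak_time = b_peak_t[idx], peak_value = b_peak_v[idx],
    trough_time = b_trough_t[idx], trough_value = b_trough_v[idx],
    vt_signal = b_vt[idx], is_sniff = b_sniff[idx], is_exp = b_exp[idx]
  )

  # realized sniff intervals (first to last modulated breath)
  sn_list <- lapply(sniff_onsets, function(o) {
    sel <- breaths$onset >= o & breaths$onset < o + config$sniff_duration
    if (!any(sel)) return(NULL)
    data.frame(onset = min(breaths$onset[sel]),
               end = max(breaths$onset[sel] + breaths$duration[sel]))
  })
  sniffs <- do.call(rbind, sn_list)
  if (is.null(sniffs)) sniffs <- data.frame(onset = numeric(0), end = numeric(0))

  keep_exp <- exp_used & !is.na(exp_truth_onset)
  expirations <- data.frame(onset = exp_truth_onset[keep_exp],
                            co2 = exp_co2[keep_exp])

  movements <- data.frame(onset = mov_onsets,
                          end = mov_onsets + config$movement_duration)

  pressure <- pressure + stats::rnorm(n, 0, config$wbp_noise * a_base)
  mov_channel <- stats::rnorm(n, 0, 0.02 * a_base)
  for (o in mov_onsets) {
    j0 <- max(1L, as.integer(floor(o * rate)) + 1L)
    j1 <- min(n, as.integer(floor((o + config$movement_duration) * rate)))
    if (j1 >= j0) {
      burst_p <- stats::rnorm(j1 - j0 + 1L, 0, config$movement_amp * a_base)
      burst_m <- stats::rnorm(j1 - j0 + 1L, 0, config$movement_amp * a_base)
      pressure[j0:j1] <- pressure[j0:j1] + burst_p
      mov_channel[j0:j1] <- mov_channel[j0:j1] + burst_m
    }
  }

  trace <- pleth_trace(pressure, rate = rate, body_mass = config$body_mass,
                       calibration = config$calibration)

  traj <- data.frame(
    time = tg,
    fr_target = config$base_fr * mult_at(tg, fr_m, fr_start) *
      (1 + config$fr_wander_sd * zs),
    vt_target = base_vt_signal * mult_at(tg, vt_m, vt_start) *
      config$calibration / config$body_mass
  )

  list(
    trace = trace,
    movement_channel = mov_channel,
    protocol = recorded_protocol(config),
    truth = list(
      breaths = breaths,
      sniffs = sniffs,
      expirations = expirations,
      movements = movements,
      epochs = ep,
      wander = data.frame(time = tg, z = zs),
      trajectories = traj
    )
  )
}
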