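test_that("triggered average of a flat trace is identically zero", {
  tr <- compute_dff(calcium_trace(rep(60, 1800), rate = 15), c(0, 60))
  ta <- triggered_average(tr, c(20, 40, 60, 80), window_s = 2)
  expect_true(all(abs(ta$mean) < 1e-12))
  expect_equal(ta$n, 4L)
  expect_true(0 %in% ta$lag)
})

test_that("events aligned to transient peaks put the average peak at lag zero", {
  sim <- sim_neuron_dff("T", seed = 91)
  peaks <- sim$events + 0.465  # analytic peak offset of the default kernel
  peaks <- peaks[peaks > 3 & peaks < 717]
  ta <- triggered_average(sim$trace, peaks, window_s = 2)
  expect_lt(abs(ta$lag[which.max(ta$mean)]), 0.15)
  expect_gt(max(ta$mean), 0.5)
})

test_that("triggered averaging is linear and drops clipped events", {
  tr1 <- sim_neuron_dff("T", seed = 92)$trace
  tr2 <- sim_neuron_dff("NC", seed = 93)$trace
  mix <- tr1
  mix$dff <- 2 * tr1$dff + 0.5 * tr2$dff
  ev <- c(-1, 50, 100, 150, 719.9)  # first and last clipped
  ta1 <- triggered_average(tr1, ev)
  ta2 <- triggered_average(tr2, ev)
  tam <- triggered_average(mix, ev)
  expect_equal(tam$mean, 2 * ta1$mean + 0.5 * ta2$mean, tolerance = 1e-9)
  expect_equal(ta1$n, 3L)
  expect_equal(ta1$n_dropped, 2L)
  expect_error(triggered_average(tr1, c(-10, 1000)), "window")
})

test_that("shuffled events stay inside the null band almost everywhere", {
  sim <- sim_neuron_dff("T", seed = 94)
  set.seed(123)
  sh <- runif(150, 5, 715)
  ta <- triggered_average(sim$trace, sh, window_s = 2)
  band <- 2 * ta$sd / sqrt(ta$n)
  expect_lte(mean(abs(ta$mean) > band), 0.10)
})

test_that("onset latency recovers configured leads and degenerate zero lead", {
  # calcium onsets exactly at event times -> lead ~ 0
  rate <- 15
  tt <- (0:(720 * rate - 1)) / rate
  evs <- seq(30, 690, by = 15)
  sig <- capnotrace:::events_to_dff(evs, rep(1, length(evs)), tt, 0.2, 1.5)
  tr <- compute_dff(calcium_trace((1 + sig) * 100, rate = rate), c(0, 20))
  lat0 <- onset_latency(tr, evs)
  expect_equal(lat0$n_matched, length(evs))
  expect_lt(abs(lat0$median_lead), 0.1)
  # histogram counts account for every matched event
  expect_equal(sum(lat0$histogram$counts), lat0$n_matched)

  # configured leads recovered across the plausible range; the noise-free
  # frame-quantized construction carries up to ~1.5 frames of onset
  # quantization, so allow 0.15 s here (the generator-based recovery test
  # below holds the 0.1 s bound)
  for (lead in c(0.2, 0.5, 1.0)) {
    sig2 <- capnotrace:::events_to_dff(evs - lead + 0.037,
                                       rep(1, length(evs)), tt, 0.2, 1.5)
    tr2 <- compute_dff(calcium_trace((1 + sig2) * 100, rate = rate),
                       c(0, 20))
    lat <- onset_latency(tr2, evs + 0.037)
    expect_lt(abs(lat$mean_lead - lead), 0.15)
    expect_lt(lat$sign_p, 0.01)
  }
})

test_that("latency estimation on generator expiratory neurons is unbiased", {
  cfg <- sim_config(protocol_levels = c(0, 6, 9, 0),
                    epoch_durations = c(180, 420, 420, 180),
                    exp_rate_per_co2 = 1.4, seed = 3,
                    indicator = "GCaMP6f")
  for (lead in c(0.3, 0.5)) {
    tpl <- neuron_template("Exp",
                           event_lead = c("6" = lead, "9" = lead),
                           event_lead_sd = 0.05)
    ds <- simulate_population(c(Exp = 3), cfg, templates = list(Exp = tpl))
    w <- epoch_windows(ds$protocol)
    br <- detect_breaths(ds$wbp)
    mv <- movement_sonogram(ds$wbp)$events
    ex <- detect_active_expiration(ds$wbp, br,
                                   baseline_window = c(w$start[1], w$end[1]),
                                   movement = mv)
    rec <- vapply(1:3, function(j) {
      tr <- compute_dff(ds$traces[[j]], c(w$start[1], w$end[1]))
      onset_latency(tr, ex)$mean_lead
    }, numeric(1))
    expect_lt(abs(mean(rec) - lead), 0.1)
  }
})

test_that("calcium-ventilation correlation behaves at its fixed points", {
  vent <- default_events()$vent
  # dff an affine function of V_T: correlation ~1 at lag 0
  vt_f <- approx(vent$time, vent$vt, xout = (0:10799) / 15, rule = 2)$y
  tr <- compute_dff(calcium_trace((1 + 2 * vt_f) * 50, rate = 15), c(0, 180))
  vc <- ventilation_correlation(tr, vent, "V_T")
  expect_gt(vc$r, 0.99)
  expect_equal(vc$best_lag, 0, tolerance = 0.51)
  expect_lt(vc$p, 0.01)

  # constant trace: undefined, flagged
  flat <- compute_dff(calcium_trace(rep(40, 10800), rate = 15), c(0, 180))
  vcf <- ventilation_correlation(flat, vent, "fR")
  expect_true(vcf$constant)
  expect_true(is.na(vcf$r))

  # independent noise: small r, null-compatible p on average
  ps <- rs <- c()
  for (s in 95:98) {
    sim <- sim_neuron_dff("NC", seed = s)
    v <- ventilation_correlation(sim$trace, vent, "fR", detrend = "epoch",
                                 protocol = default_behavior()$protocol)
    ps <- c(ps, v$p)
    rs <- c(rs, abs(v$r))
  }
  expect_gt(mean(ps), 0.2)
  expect_lt(median(rs), 0.3)
})

test_that("adapting neurons track tidal volume through the CO2 transition", {
  # the circular-shift null treats the single CO2 transition as one
  # effective sample and cannot certify a per-neuron p there, so the
  # population-level claim is tested: every adapting neuron correlates
  # positively with V_T across the 0 -> 3% transition (sign test over
  # neurons, p = 2^-6 < 0.05)
  vent <- default_events()$vent
  rs <- vapply(101:106, function(s) {
    sim <- sim_neuron_dff("E_A", seed = s)
    ventilation_correlation(sim$trace, vent, "V_T",
                            window = c(150, 260))$r
  }, numeric(1))
  expect_true(all(rs > 0))
  expect_gt(mean(rs), 0.2)
})
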