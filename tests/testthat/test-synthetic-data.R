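test_that("a fixed seed reproduces the dataset byte for byte", {
  cfg <- sim_config(seed = 7, epoch_durations = 60)
  b1 <- simulate_breathing(cfg)
  b2 <- simulate_breathing(cfg)
  expect_identical(b1$trace$samples, b2$trace$samples)
  expect_identical(b1$truth, b2$truth)

  d1 <- simulate_population(c("E_A" = 2, NC = 2), cfg)
  d2 <- simulate_population(c("E_A" = 2, NC = 2), cfg)
  expect_identical(lapply(d1$traces, `[[`, "f"),
                   lapply(d2$traces, `[[`, "f"))
  expect_identical(d1$truth$events, d2$truth$events)
})

test_that("composition is conserved exactly and bad input rejected", {
  cfg <- sim_config(seed = 3, epoch_durations = 60)
  comp <- c("E_A" = 3, I = 2, NC = 4)
  ds <- simulate_population(comp, cfg)
  expect_equal(length(ds$traces), 9L)
  expect_equal(table(ds$truth$labels$class)[names(comp)],
               table(rep(names(comp), comp))[names(comp)])
  # every trace carries exactly one label
  expect_false(anyNA(ds$truth$labels$class))
  expect_error(simulate_population(integer(0), cfg), "empty")
  expect_error(simulate_population(c("E_A" = -1), cfg), ">= 0")
  expect_error(simulate_population(c(bogus = 1), cfg), "unknown class")
  expect_error(neuron_template("bogus"), "unknown class")
})

test_that("with modulation off the breath count is forced by fR", {
  cfg <- sim_config(
    protocol_levels = 0, epoch_durations = 60, seed = 2,
    base_fr = 120, fr_mult = c("0" = 1), vt_mult = c("0" = 1),
    fr_wander_sd = 0, breath_dur_cv = 0, breath_amp_cv = 0,
    exp_depth_cv = 0, sniff_rate = 0, exp_rate_per_co2 = 0,
    movement_rate = 0, wbp_noise = 0
  )
  bh <- simulate_breathing(cfg)
  expect_equal(nrow(bh$truth$breaths), 120L)
  br <- detect_breaths(bh$trace)
  expect_equal(nrow(br), 120L)
})

test_that("an epoch too short for ten breaths is rejected", {
  cfg <- sim_config(protocol_levels = c(0, 3), epoch_durations = c(60, 2),
                    seed = 1)
  expect_error(simulate_breathing(cfg), "10 breaths")
})

test_that("single noise-free event matches the closed-form kernel to 1e-9", {
  rate <- 15
  tt <- (0:599) / rate
  sig <- capnotrace:::events_to_dff(10, 1, tt, 0.2, 1.5)
  tstar <- log(1.5 / 0.2) / (1 / 0.2 - 1 / 1.5)
  peak <- exp(-tstar / 1.5) - exp(-tstar / 0.2)
  ref <- ifelse(tt >= 10,
                (exp(-(tt - 10) / 1.5) - exp(-(tt - 10) / 0.2)) / peak, 0)
  expect_lt(max(abs(sig - ref)), 1e-9)
  expect_equal(max(sig), 1, tolerance = 1e-3)  # peak-normalized
})

test_that("downstream V_E rises at each CO2 step and partially relaxes", {
  bh <- default_behavior()
  ev <- default_events()
  vent <- ev$vent
  ep <- bh$truth$epochs
  late_mean <- function(i) {
    sel <- vent$time >= ep$start[i] + 60 & vent$time < ep$end[i]
    mean(vent$ve[sel], na.rm = TRUE)
  }
  ve <- vapply(seq_len(nrow(ep)), late_mean, numeric(1))
  # ordering follows the configured V_T x fR multipliers: 0 < 3 < 6, recovery ~ baseline
  expect_gt(ve[2], ve[1] * 1.3)
  expect_gt(ve[3], ve[2] * 1.1)
  expect_lt(ve[4], ve[2])
  # partial adaptation: onset overshoot relaxes within the epoch
  onset_sel <- vent$time >= ep$start[3] + 2 & vent$time < ep$start[3] + 20
  expect_gt(max(vent$ve[onset_sel], na.rm = TRUE), ve[3])
})

test_that("expiratory template events precede each expiration by the lead", {
  bh <- default_behavior()
  cfg <- sim_config(seed = 1)
  tpl <- neuron_template("Exp", base_rate = 0,
                         event_lead = c("3" = 0.5, "6" = 0.5),
                         event_lead_sd = 0)
  sim <- simulate_neuron(tpl, bh, cfg, seed = 99)
  exps <- bh$truth$expirations$onset
  skip_if(length(exps) == 0)
  expect_equal(length(sim$events), length(exps))
  expect_equal(sort(exps - sim$events), rep(0.5, length(exps)),
               tolerance = 1e-9)
})

test_that("every injected sniff bout clears the default detector threshold", {
  bh <- default_behavior()
  br <- default_events()$breaths
  vent <- default_events()$vent
  dt <- vent$time[2] - vent$time[1]
  thr <- 2 * stats::runmed(vent$fr, capnotrace:::odd_k(60, 1 / dt, nrow(vent)))
  sn <- bh$truth$sniffs
  for (i in seq_len(nrow(sn))) {
    sel <- which(br$onset >= sn$onset[i] & br$onset < sn$end[i] &
                   is.finite(br$fr_inst))
    thr_here <- approx(vent$time, thr, xout = sn$onset[i], rule = 2)$y
    expect_gt(max(br$fr_inst[sel]), thr_here)
  }
})

test_that("graded neurons step up with CO2 level and inhibited ones shut down", {
  cfg <- sim_config(seed = 1)
  w <- default_windows()
  eg <- sim_neuron_dff("E_G", seed = 41)
  m <- vapply(seq_len(nrow(w)), function(i) {
    t <- capnotrace:::frame_times(eg$trace)
    mean(eg$trace$dff[t >= w$start[i] & t < w$end[i]])
  }, numeric(1))
  expect_gt(m[2], m[1])   # 3% above baseline
  expect_gt(m[3], m[2])   # further increase at 6%
  expect_lt(m[4], m[2])   # returns toward baseline

  inh <- sim_neuron_dff("I", seed = 42)
  t <- capnotrace:::frame_times(inh$trace)
  m_i <- vapply(seq_len(nrow(w)), function(i) {
    mean(inh$trace$dff[t >= w$start[i] & t < w$end[i]])
  }, numeric(1))
  expect_lt(m_i[2], m_i[1])
  expect_lt(m_i[3], m_i[1])
})

test_that("tonic neurons have statistically flat epoch means", {
  # noise-free trace; epoch means differ only by Poisson counting, so they
  # agree within a few standard errors of the event count
  cfg <- sim_config(seed = 1, ca_noise = 0, drift_amp = 0)
  bh <- default_behavior()
  tpl <- neuron_template("T")
  sim <- simulate_neuron(tpl, bh, cfg, seed = 5)
  w <- default_windows()
  t <- capnotrace:::frame_times(sim$trace)
  dff <- sim$trace$f / 100
  m <- vapply(seq_len(nrow(w)), function(i) {
    mean(dff[t >= w$start[i] & t < w$end[i]])
  }, numeric(1))
  # expected elevation per epoch: rate x kernel integral; Poisson SE
  n_exp <- tpl$base_rate * 180
  se <- sqrt(n_exp) / n_exp * (mean(m) - 1)
  expect_lt(max(m) - min(m), 6 * se)
})
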