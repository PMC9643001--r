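test_that("dF/F is unit for constant traces and invariant under gain", {
  tr <- calcium_trace(rep(50, 300), rate = 15)
  tr <- compute_dff(tr, c(0, 10))
  expect_true(all(abs(tr$dff - 1) < 1e-12))

  sim <- sim_neuron_dff("T", seed = 21)
  tr3 <- sim$trace
  tr3$f <- 3 * tr3$f
  w <- default_windows()
  tr3 <- compute_dff(tr3, c(w$start[1], w$end[1]))
  expect_equal(tr3$dff, sim$trace$dff, tolerance = 1e-12)

  bad <- calcium_trace(rep(-5, 300), rate = 15)
  expect_error(compute_dff(bad, c(0, 10)), "positive")
  expect_error(compute_dff(calcium_trace(1:300, rate = 15), c(100, 200)),
               "window")
})

test_that("a generated event's peak dF/F matches the configured amplitude", {
  tr <- single_event_trace(amp = 0.8, noise = 0.05, seed = 8)
  ev <- detect_transients(tr)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$amplitude, 0.8, tolerance = 0.15)
})

test_that("background subtraction removes a shared artefact", {
  rate <- 15
  tt <- (0:1199) / rate
  art <- numeric(1200)
  art[700:740] <- 0.6   # artefacts clear of the transient, so the
  art[1000:1030] <- -0.3  # noise-free correction is exact
  sig <- ca_kernel(tt - 20, 0.2, 1.5)
  roi <- compute_dff(calcium_trace((1 + sig + art) * 100, rate = rate),
                     c(0, 10))
  bg <- compute_dff(calcium_trace((1 + art) * 80, rate = rate), c(0, 10))

  corrected <- subtract_background(roi, bg)
  clean <- (1 + sig) * 100 / roi$f0
  expect_lt(max(abs(corrected$dff - clean)), 0.01)  # exact up to F0 rounding
  expect_true(corrected$background_subtracted)
  # artefact power reduced at least 10-fold
  artf <- art != 0
  expect_lt(mean((corrected$dff[artf] - clean[artf])^2),
            mean((roi$dff[artf] - clean[artf])^2) / 10)

  # zero background: identity
  bg0 <- compute_dff(calcium_trace(rep(80, 1200), rate = rate), c(0, 10))
  same <- subtract_background(roi, bg0)
  expect_equal(as.numeric(same$dff), as.numeric(roi$dff), tolerance = 1e-9)

  # mismatched grids rejected
  short <- compute_dff(calcium_trace(rep(80, 600), rate = rate), c(0, 10))
  expect_error(subtract_background(roi, short), "grid")
})

test_that("transient detection is silent on flat noise and recalls generated events", {
  flat <- sim_neuron_dff("NC", seed = 31, qc_defect = "flat")
  expect_equal(nrow(detect_transients(flat$trace)), 0L)

  hits <- total <- 0
  for (s in 1:3) {
    sim <- sim_neuron_dff("T", seed = 300 + s)
    det <- detect_transients(sim$trace)
    hits <- hits + sum(vapply(sim$events, function(e) {
      any(abs(det$onset - e) < 0.3)
    }, logical(1)))
    total <- total + length(sim$events)
  }
  expect_gte(hits / total, 0.9)
})

test_that("events closer than the rise merge into one detection", {
  rate <- 15
  tt <- (0:1799) / rate
  two <- capnotrace:::events_to_dff(c(30, 30.1), c(1, 1), tt, 0.2, 1.5)
  tr <- compute_dff(calcium_trace((1 + two) * 100, rate = rate), c(0, 20))
  expect_equal(nrow(detect_transients(tr)), 1L)
  # but events with separated rises resolve
  sep <- capnotrace:::events_to_dff(c(30, 31.5), c(1, 1), tt, 0.2, 1.5)
  tr2 <- compute_dff(calcium_trace((1 + sep) * 100, rate = rate), c(0, 20))
  expect_equal(nrow(detect_transients(tr2)), 2L)
})

test_that("noise-free kinetics recover the decay constant within 1%", {
  tr <- single_event_trace(decay_tau = 1.5)
  ev <- detect_transients(tr)
  k <- fit_transient_kinetics(tr, ev[1, ])
  expect_true(k$converged)
  expect_lt(abs(k$decay_tau - 1.5) / 1.5, 0.01)
  expect_equal(k$rise_time, 0.245, tolerance = 0.25)
})

test_that("median decay-constant error stays within 10% at default noise", {
  errs <- c()
  for (s in 1:8) {
    sim <- sim_neuron_dff("NC", seed = 600 + s)
    kin <- transient_kinetics(sim$trace)
    kin <- kin[kin$converged & kin$gof > 0.8, ]
    errs <- c(errs, abs(kin$decay_tau - 1.5) / 1.5)
  }
  expect_gt(length(errs), 30)
  expect_lte(median(errs), 0.10)
})

test_that("transient shape does not change across hypercapnia epochs", {
  bh <- default_behavior()
  sim <- sim_neuron_dff("E_A", seed = 11)
  kin <- transient_kinetics(sim$trace, protocol = bh$protocol)
  kin <- kin[kin$converged & kin$gof > 0.8, ]
  skip_if(length(unique(kin$co2)) < 2)
  p <- kruskal.test(kin$decay_tau, factor(kin$co2))$p.value
  expect_gt(p, 0.05)
})

test_that("four-criterion QC admits clean cells and rejects each defect", {
  mv <- default_events()$movement
  clean <- sim_neuron_dff("E_A", seed = 51)
  q <- qc_cell(clean$trace, mv)
  expect_true(q$eligible)

  flat <- sim_neuron_dff("NC", seed = 52, qc_defect = "flat")
  qf <- qc_cell(flat$trace, mv)
  expect_false(qf$eligible)
  expect_false(qf$criteria[["signal"]])

  moved <- sim_neuron_dff("NC", seed = 53, qc_defect = "movement")
  qm <- qc_cell(moved$trace, mv)
  expect_false(qm$eligible)
  expect_false(qm$criteria[["movement"]])

  drift <- sim_neuron_dff("T", seed = 54, qc_defect = "drift")
  qd <- qc_cell(drift$trace, mv)
  expect_false(qd$eligible)
  expect_false(qd$criteria[["focal"]])

  morph <- sim_neuron_dff("NC", seed = 55, qc_defect = "morphology")
  qmo <- qc_cell(morph$trace, mv)
  expect_false(qmo$eligible)
  expect_false(qmo$criteria[["morphology"]])
})

test_that("QC verdicts are invariant under multiplicative gain", {
  mv <- default_events()$movement
  w <- default_windows()
  for (s in c(61, 62)) {
    sim <- sim_neuron_dff("T", seed = s)
    q1 <- qc_cell(sim$trace, mv)
    tr2 <- sim$trace
    tr2$f <- 5 * tr2$f
    tr2 <- compute_dff(tr2, c(w$start[1], w$end[1]))
    q2 <- qc_cell(tr2, mv)
    expect_identical(q1$criteria, q2$criteria)
  }
})
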