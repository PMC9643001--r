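test_that("a pure sinusoid segments into the forced breath count", {
  rate <- 200
  tt <- (0:(10 * rate - 1)) / rate
  x <- sin(2 * pi * 4 * tt)  # 4 Hz, 10 s -> 40 cycles
  tr <- pleth_trace(x, rate = rate, body_mass = 25)
  br <- detect_breaths(tr)
  expect_equal(nrow(br), 40L, tolerance = 0)
  expect_equal(median(br$fr_inst, na.rm = TRUE), 240, tolerance = 0.02)
})

test_that("flat and zero-amplitude traces yield empty tables, not errors", {
  tr <- pleth_trace(rep(0, 2000), rate = 200)
  expect_equal(nrow(detect_breaths(tr)), 0L)
  tr2 <- pleth_trace(rep(3.2, 2000), rate = 200)
  expect_equal(nrow(detect_breaths(tr2)), 0L)
})

test_that("breath detection matches generator ground truth", {
  bh <- default_behavior()
  br <- default_events()$breaths
  truth <- bh$truth$breaths
  half <- median(truth$duration) / 2
  recall <- mean(vapply(truth$onset, function(o) {
    any(abs(br$onset - o) < half)
  }, logical(1)))
  precision <- mean(vapply(br$onset, function(o) {
    any(abs(truth$onset - o) < half)
  }, logical(1)))
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("breath count is invariant under gain and offset", {
  bh <- default_behavior()
  n0 <- nrow(detect_breaths(bh$trace))
  tr2 <- bh$trace
  tr2$samples <- 3.7 * tr2$samples + 11
  expect_equal(nrow(detect_breaths(tr2)), n0)
})

test_that("V_E is identically the product of V_T and fR", {
  vent <- default_events()$vent
  expect_identical(vent$ve, vent$vt * vent$fr)

  # constant breathing: V_T 0.25, fR 120 -> V_E 30 everywhere
  onsets <- seq(0, 59.5, by = 0.5)
  b <- data.frame(
    onset = onsets, peak_time = onsets + 0.1, peak_value = 1,
    trough_time = onsets + 0.3, trough_value = -0.25,
    vt = 6.25, vt_per_g = 0.25, duration = 0.5, fr_inst = 120
  )
  class(b) <- c("breath_table", "data.frame")
  v <- compute_ventilation(b, window_s = 2, end_time = 58)
  mid <- v$time > 2 & v$time < 56
  expect_equal(v$vt[mid], rep(0.25, sum(mid)), tolerance = 1e-9)
  expect_equal(v$fr[mid], rep(120, sum(mid)), tolerance = 1e-9)
  expect_equal(v$ve[mid], rep(30, sum(mid)), tolerance = 1e-9)
  expect_error(compute_ventilation(b, window_s = 0.2), "cycle")
})

test_that("doubling pressure doubles V_T and V_E but not fR", {
  bh <- default_behavior()
  tr2 <- bh$trace
  tr2$samples <- 2 * tr2$samples
  total <- length(tr2$samples) / tr2$rate
  v1 <- compute_ventilation(detect_breaths(bh$trace), end_time = total)
  v2 <- compute_ventilation(detect_breaths(tr2), end_time = total)
  mid <- v1$time > 10 & v1$time < total - 10
  expect_equal(v2$vt[mid], 2 * v1$vt[mid], tolerance = 0.02)
  expect_equal(v2$fr[mid], v1$fr[mid], tolerance = 0.02)
  expect_equal(v2$ve[mid], 2 * v1$ve[mid], tolerance = 0.04)
})

test_that("sniff bouts are recovered at the injected times", {
  bh <- default_behavior()
  ev <- default_events()
  truth <- bh$truth$sniffs
  sn <- ev$sniffs
  expect_equal(nrow(sn), nrow(truth))
  err <- vapply(truth$onset, function(o) min(abs(sn$onset - o)), numeric(1))
  # onset refined to the first supra-threshold breath: within one cycle
  expect_lt(max(err), 0.35)
})

test_that("sniff detection degenerates sensibly", {
  vent <- default_events()$vent
  # absolute threshold far above any fR: nothing
  none <- detect_sniff_bouts(vent, fr_threshold = 5000)
  expect_equal(nrow(none), 0L)
  # threshold 0: one bout spanning the record
  all_run <- detect_sniff_bouts(vent, fr_threshold = 0)
  expect_equal(nrow(all_run), 1L)
  expect_lt(all_run$onset[1], 1)
  expect_gt(all_run$onset[1] + all_run$duration[1], max(vent$time) - 1)
})

test_that("active expiration detection recovers injected events only", {
  bh <- default_behavior()
  ev <- default_events()
  truth <- bh$truth$expirations
  ex <- ev$exps
  expect_equal(nrow(ex), nrow(truth))
  err <- vapply(truth$onset, function(o) min(abs(ex$onset - o)), numeric(1))
  expect_lt(max(err), 0.05)
  expect_equal(attr(ex, "baseline"), "window")
})

test_that("expiration detector honours degenerate thresholds and monotonicity", {
  bh <- default_behavior()
  br <- default_events()$breaths
  mv <- default_events()$movement
  # all troughs equal: no events at any positive threshold
  rate <- 200
  tt <- (0:(30 * rate - 1)) / rate
  tru <- pleth_trace(sin(2 * pi * 3 * tt), rate = rate)
  bru <- detect_breaths(tru)
  expect_equal(nrow(detect_active_expiration(tru, bru, 1)), 0L)
  # threshold 0 flags every breath
  all_b <- detect_active_expiration(tru, bru, 0)
  expect_equal(nrow(all_b), nrow(bru))
  # relaxing the threshold only adds events
  e4 <- detect_active_expiration(bh$trace, br, 4, baseline_window = c(0, 180),
                                 movement = mv)
  e2 <- detect_active_expiration(bh$trace, br, 2, baseline_window = c(0, 180),
                                 movement = mv)
  expect_true(all(e4$onset %in% e2$onset))
  # whole-record fallback is flagged
  ewr <- detect_active_expiration(bh$trace, br, 4)
  expect_equal(attr(ewr, "baseline"), "whole-record")
})

test_that("movement sonogram finds bouts on both channels and stays silent otherwise", {
  bh <- default_behavior()
  truth <- bh$truth$movements
  skip_if(nrow(truth) == 0)
  wbp <- movement_sonogram(bh$trace)
  mov <- movement_sonogram(bh$movement_channel, rate = bh$trace$rate)
  for (det in list(wbp$events, mov$events)) {
    expect_equal(nrow(det), nrow(truth))
    jacc <- vapply(seq_len(nrow(truth)), function(i) {
      ov <- pmin(det$onset + det$duration, truth$end[i]) -
        pmax(det$onset, truth$onset[i])
      j <- which.max(ov)
      un <- max(det$onset[j] + det$duration[j], truth$end[i]) -
        min(det$onset[j], truth$onset[i])
      max(ov[j], 0) / un
    }, numeric(1))
    expect_gte(min(jacc), 0.8)
  }
  # the two channels agree on the bout count (WBP vs Mov sonogram)
  expect_equal(nrow(wbp$events), nrow(mov$events))

  # silent channel: no bouts; window longer than record: error
  expect_equal(nrow(movement_sonogram(rnorm(4000, 0, 1e-6) * 0,
                                      rate = 200)$events), 0L)
  expect_error(movement_sonogram(rnorm(100), rate = 200, window_s = 2),
               "window")
})
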