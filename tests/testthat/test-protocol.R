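test_that("gas protocol validates its epoch structure", {
  p <- gas_protocol(c(0, 3, 6, 0), 180, analyzer_delay = 17.5)
  expect_s3_class(p, "gas_protocol")
  expect_equal(nrow(p), 4L)
  expect_equal(p$end - p$start, rep(180, 4))
  expect_error(gas_protocol(c(3, 6), 180), "baseline")
  expect_error(gas_protocol(c(0, 3), c(180, -5)))
  expect_error(gas_protocol(c(0, 3), 180, analyzer_delay = -1), ">= 0")
})

test_that("delay correction shifts interior boundaries only", {
  p <- gas_protocol(c(0, 3, 6, 0), 180, analyzer_delay = 20)
  # readout boundaries lag the chamber gas
  p$start <- c(0, 200, 380, 560)
  p$end <- c(200, 380, 560, 720)
  w <- epoch_windows(p)
  expect_equal(w$start, c(0, 180, 360, 540))
  expect_equal(w$end, c(180, 360, 540, 720))
  # no delay: identity
  p0 <- gas_protocol(c(0, 6), c(100, 100))
  expect_equal(epoch_windows(p0)$start, p0$start)
})

test_that("CO2 lookup respects corrected windows and half-open intervals", {
  p <- gas_protocol(c(0, 3, 6, 0), 180, analyzer_delay = 17.5)
  p$start <- c(0, 197.5, 377.5, 557.5)
  p$end <- c(197.5, 377.5, 557.5, 720)
  lev <- capnotrace:::co2_at(p, c(0, 179.9, 180, 359.9, 360, 540, 719))
  expect_equal(lev, c(0, 0, 3, 3, 6, 0, 0))
})
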