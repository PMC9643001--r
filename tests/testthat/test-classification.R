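test_that("constant dF/F yields zero epoch deltas", {
  bh <- default_behavior()
  tr <- calcium_trace(rep(80, 720 * 15), rate = 15)
  tr <- compute_dff(tr, c(0, 180))
  st <- epoch_stats(tr, bh$protocol)
  expect_equal(st$delta_lo, 0, tolerance = 1e-12)
  expect_equal(st$delta_hi, 0, tolerance = 1e-12)
})

test_that("epoch deltas separate graded and inhibited generator neurons", {
  eg <- sim_neuron_dff("E_G", seed = 71)
  bh <- default_behavior()
  st <- epoch_stats(eg$trace, bh$protocol)
  expect_gt(st$delta_lo, 0)
  expect_gt(st$delta_hi, st$delta_lo)

  inh <- sim_neuron_dff("I", seed = 72)
  sti <- epoch_stats(inh$trace, bh$protocol)
  expect_lt(sti$delta_lo, 0)
  expect_lt(sti$delta_hi, 0)
})

test_that("two-component regions follow the geometry of the deltas", {
  expect_equal(two_component(c(0, 0))$region, "near-origin")
  expect_equal(two_component(c(2, 1))$region, "below-identity")
  expect_equal(two_component(c(1, 2))$region, "above-identity")
  expect_equal(two_component(c(-1, -2))$region, "negative-quadrant")
  expect_equal(two_component(c(0.1, 0.05), eps = 0.25)$region, "near-origin")
})

test_that("an epoch swallowed by movement renders the neuron unclassifiable", {
  bh <- default_behavior()
  sim <- sim_neuron_dff("T", seed = 73)
  blanket <- event_series("movement", 180, duration = 180)
  st <- epoch_stats(sim$trace, bh$protocol, movement = blanket)
  expect_true(any(st$epochs$missing))
  cls <- classify_neuron(st)
  expect_equal(cls$label, "unclassifiable")
})

test_that("a mixed population is recovered with high accuracy", {
  comp <- c("E_A" = 5, "E_G" = 3, I = 3, T = 3, Sn = 2, NC = 5, "NC-RR" = 4)
  ds <- simulate_population(comp, sim_config(seed = 11))
  cls <- classify_population(ds)
  expect_equal(nrow(cls$table), sum(comp))
  expect_equal(sum(cls$counts), sum(cls$table$eligible))
  acc <- mean(ds$truth$labels$class == cls$table$label)
  expect_gte(acc, 0.85)
  # exactly one label per neuron, composition sums to population size
  expect_false(anyNA(cls$table$label))
  expect_equal(cls$modulated$strict,
               as.integer(sum(cls$counts[c("E_A", "E_G", "I")])))
})

test_that("classification is invariant under gain and frame-rate resampling", {
  bh <- default_behavior()
  ev <- default_events()
  classify_one <- function(tr) {
    trans <- detect_transients(tr)
    st <- epoch_stats(tr, bh$protocol, movement = ev$movement,
                      transients = trans)
    sn <- onset_latency(tr, ev$sniffs, transients = trans)
    ex <- onset_latency(tr, ev$exps, transients = trans)
    fr <- ventilation_correlation(tr, ev$vent, "fR", detrend = "epoch",
                                  protocol = bh$protocol)
    classify_neuron(st, sn, ex, fr)$label
  }
  w <- default_windows()
  for (cl in c("E_G", "I")) {
    sim <- sim_neuron_dff(cl, seed = 81)
    lab0 <- classify_one(sim$trace)
    expect_equal(lab0, cl)
    # gain
    g <- sim$trace
    g$f <- 2.5 * g$f
    g <- compute_dff(g, c(w$start[1], w$end[1]))
    expect_equal(classify_one(g), lab0)
    # resample 15 -> 10 and 15 -> 20 frames/s
    t0 <- capnotrace:::frame_times(sim$trace)
    for (r2 in c(10, 20)) {
      t2 <- seq(0, max(t0), by = 1 / r2)
      f2 <- approx(t0, sim$trace$f, xout = t2, rule = 2)$y
      tr2 <- compute_dff(calcium_trace(f2, rate = r2),
                         c(w$start[1], w$end[1]))
      expect_equal(classify_one(tr2), lab0)
    }
  }
})

test_that("an empty dataset classifies to an empty table without error", {
  cfg <- sim_config(seed = 2, epoch_durations = 60)
  ds <- simulate_population(c(NC = 0L), cfg)
  cls <- classify_population(ds)
  expect_equal(nrow(cls$table), 0L)
  expect_equal(sum(cls$counts), 0L)
  expect_equal(cls$qc$total, 0L)
})
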