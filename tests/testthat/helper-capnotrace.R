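# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# default-condition breathing recording (seed 1) shared across files
default_behavior <- function() {
  memo("behavior1", simulate_breathing(sim_config(seed = 1)))
}

default_windows <- function() {
  epoch_windows(default_behavior()$protocol)
}

# behavioural detections on the shared recording
default_events <- function() {
  memo("events1", {
    bh <- default_behavior()
    br <- detect_breaths(bh$trace)
    total <- length(bh$trace$samples) / bh$trace$rate
    vent <- compute_ventilation(br, end_time = total)
    mv <- movement_sonogram(bh$trace)$events
    w <- default_windows()
    list(
      breaths = br,
      vent = vent,
      movement = mv,
      sniffs = detect_sniff_bouts(vent, movement = mv),
      exps = detect_active_expiration(bh$trace, br,
                                      baseline_window = c(w$start[1], w$end[1]),
                                      movement = mv)
    )
  })
}

# one simulated neuron of a class on the shared recording, with dF/F
sim_neuron_dff <- function(class_label, seed, config = sim_config(seed = 1),
                           template = NULL, qc_defect = "none") {
  bh <- default_behavior()
  tpl <- template %||% neuron_template(class_label)
  sim <- simulate_neuron(tpl, bh, config, seed = seed, qc_defect = qc_defect)
  w <- default_windows()
  sim$trace <- compute_dff(sim$trace, c(w$start[1], w$end[1]))
  sim
}

# a quiet single-event trace: one unit-amplitude kernel on a flat baseline
single_event_trace <- function(decay_tau = 1.5, rise_tau = 0.2, rate = 15,
                               duration = 120, onset = 30, noise = 0,
                               amp = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tt <- (seq_len(duration * rate) - 1) / rate
  dff <- 1 + amp * ca_kernel(tt - onset, rise_tau, decay_tau)
  if (noise > 0) dff <- dff + rnorm(length(tt), 0, noise)
  compute_dff(calcium_trace(dff * 100, rate = rate), c(0, onset - 5))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rtn_composition <- c("E_A" = 27, "E_G" = 4, "I" = 5, "Sn" = 3, "T" = 5,
                     "NC" = 35, "NC-RR" = 19)
raphe_composition <- c("E_G" = 8, "E_A" = 4, "I" = 10, "NC" = 4)
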