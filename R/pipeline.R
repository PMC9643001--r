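#' Pipeline run configuration
#'
#' Validated configuration for an end-to-end run: either a simulation
#' recipe or a directory of input files, plus all module thresholds, the
#' master seed and an output directory. Unknown arguments are rejected.
#'
#' @param composition Named class counts to simulate (exclusive with
#'   `input_dir`).
#' @param sim A [sim_config()] (built with `seed` when omitted).
#' @param input_dir Directory containing a dataset written by
#'   [write_dataset()].
#' @param qc_defects Optional defect counts forwarded to
#'   [simulate_population()].
#' @param classify A [classify_config()].
#' @param qc A [qc_config()].
#' @param seed Master seed.
#' @param out_dir Output directory (`NULL`: nothing written).
#' @return A list of class `run_config`.
#' @export
run_config <- function(composition = NULL, sim = NULL, input_dir = NULL,
                       qc_defects = NULL, classify = classify_config(),
                       qc = qc_config(), seed = 1L, out_dir = NULL) {
  if (is.null(composition) && is.null(input_dir)) {
    stop("provide either a composition to simulate or an input_dir")
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop("input directory not found: ", input_dir)
  }
  sim <- sim %||% if (!is.null(composition)) sim_config(seed = seed)
  structure(list(composition = composition, sim = sim,
                 input_dir = input_dir, qc_defects = qc_defects,
                 classify = classify, qc = qc, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Simulates or loads a dataset, runs plethysmography segmentation, QC,
#' classification and event-triggered latency analysis, and assembles a
#' run report. Identical configuration and seed give an identical report.
#' A stage failure aborts with the stage named.
#'
#' @param config A [run_config()].
#' @return Object of class `run_report`: QC accounting, per-label
#'   composition, both CO2-modulated accountings, per-CO2-level latency
#'   summaries for event-locked neurons, the file manifest, a config
#'   echo and the package version.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  dataset <- stage("input", {
    if (!is.null(config$input_dir)) {
      read_dataset(config$input_dir)
    } else {
      simulate_population(config$composition, config$sim,
                          qc_defects = config$qc_defects)
    }
  })
  cls <- stage("classification",
               classify_population(dataset, config$classify, config$qc))

  latency <- stage("latency", {
    out <- list()
    for (lbl in c("Exp", "Sn")) {
      ids <- cls$table$roi_id[cls$table$label == lbl]
      if (!length(ids)) next
      evs <- if (lbl == "Exp") cls$events$expirations else cls$events$sniffs
      if (!nrow(evs)) next
      w <- epoch_windows(dataset$protocol)
      per <- lapply(ids, function(id) {
        j <- which(vapply(dataset$traces, function(x) x$roi_id,
                          character(1)) == id)
        tr <- compute_dff(dataset$traces[[j]], c(w$start[1L], w$end[1L]))
        onset_latency(tr, evs, protocol = dataset$protocol)
      })
      lev <- do.call(rbind, lapply(per, function(p) p$per_level))
      by_level <- if (!is.null(lev)) {
        stats::aggregate(cbind(mean_lead, median_lead) ~ co2, lev, mean)
      }
      out[[lbl]] <- list(
        n_neurons = length(ids),
        mean_lead = mean(vapply(per, function(p) p$mean_lead, numeric(1)),
                         na.rm = TRUE),
        median_leads = vapply(per, function(p) p$median_lead, numeric(1)),
        by_level = by_level
      )
    }
    out
  })

  manifest <- character(0)
  if (!is.null(config$out_dir)) {
    manifest <- stage("output", {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      f1 <- file.path(config$out_dir, "classification.csv")
      utils::write.csv(cls$table, f1, row.names = FALSE)
      f2 <- file.path(config$out_dir, "composition.json")
      jsonlite::write_json(as.list(cls$counts), f2, auto_unbox = TRUE)
      f3 <- file.path(config$out_dir, "two_component.png")
      grDevices::png(f3, width = 700, height = 600)
      tryCatch(plot(cls, main = "Two-component analysis"),
               finally = grDevices::dev.off())
      c(f1, f2, f3)
    })
  }

  structure(list(
    qc = cls$qc,
    composition = as.list(cls$counts),
    modulated = cls$modulated,
    latency = latency,
    manifest = manifest,
    config = list(seed = config$seed,
                  simulated = is.null(config$input_dir),
                  n_traces = length(dataset$traces)),
    version = as.character(utils::packageVersion("capnotrace"))
  ), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Run report (capnotrace %s)\n", x$version))
  cat(sprintf("  QC: %d/%d eligible\n", x$qc$eligible, x$qc$total))
  cat("  Composition:",
      paste(sprintf("%s=%d", names(x$composition),
                    unlist(x$composition)), collapse = " "), "\n")
  cat(sprintf("  CO2-modulated: %d strict, %d incl. sniff-coding\n",
              x$modulated$strict, x$modulated$with_sniff))
  invisible(x)
}

#' Write a dataset to plain-text files
#'
#' Writes `wbp.csv` (`time_s`, `pressure`), `ca.csv` (`time_s` plus one
#' column per ROI, raw fluorescence), `events.csv` (`time_s`, `type` of
#' ground-truth behavioural events), `truth.json` (labels and per-neuron
#' event times), `protocol.yaml` and `config.yaml`.
#'
#' @param dataset A `ca_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "ca_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wbp_f <- file.path(dir, "wbp.csv")
  utils::write.csv(data.frame(time_s = pleth_times(dataset$wbp),
                              pressure = dataset$wbp$samples),
                   wbp_f, row.names = FALSE)
  ca <- if (length(dataset$traces)) {
    data.frame(time_s = frame_times(dataset$traces[[1L]]))
  } else {
    data.frame(time_s = numeric(0))
  }
  for (tr in dataset$traces) ca[[tr$roi_id]] <- tr$f
  ca_f <- file.path(dir, "ca.csv")
  utils::write.csv(ca, ca_f, row.names = FALSE)

  bh <- dataset$truth$behavior
  ev <- rbind(
    data.frame(time_s = bh$sniffs$onset, type = "sniff"),
    data.frame(time_s = bh$expirations$onset, type = "expiration"),
    data.frame(time_s = bh$movements$onset, type = "movement")
  )
  ev_f <- file.path(dir, "events.csv")
  utils::write.csv(ev[order(ev$time_s), ], ev_f, row.names = FALSE)

  truth_f <- file.path(dir, "truth.json")
  jsonlite::write_json(list(labels = dataset$truth$labels,
                            events = dataset$truth$events),
                       truth_f, digits = NA)

  proto_f <- file.path(dir, "protocol.yaml")
  yaml::write_yaml(list(
    co2 = dataset$protocol$co2,
    start = dataset$protocol$start,
    end = dataset$protocol$end,
    analyzer_delay = attr(dataset$protocol, "analyzer_delay")
  ), proto_f)

  cfg_f <- file.path(dir, "config.yaml")
  cfg <- unclass(dataset$config)
  cfg$fr_mult <- as.list(cfg$fr_mult)
  cfg$vt_mult <- as.list(cfg$vt_mult)
  yaml::write_yaml(cfg, cfg_f)
  invisible(c(wbp_f, ca_f, ev_f, truth_f, proto_f, cfg_f))
}

#' Read a dataset from plain-text files
#'
#' Reads the CSV/YAML dialects written by [write_dataset()] (or any files
#' matching them) and validates: monotonic time axes, contiguous
#' non-overlapping protocol epochs, a 0% first epoch. Malformed input is
#' rejected with the offending file and problem named.
#'
#' @param dir Directory containing `wbp.csv`, `ca.csv`, `protocol.yaml`
#'   and `config.yaml` (plus optional `events.csv`, `truth.json`).
#' @return A `ca_dataset`.
#' @export
read_dataset <- function(dir) {
  need <- c("wbp.csv", "ca.csv", "protocol.yaml", "config.yaml")
  for (f in need) {
    if (!file.exists(file.path(dir, f))) {
      stop("missing input file: ", file.path(dir, f))
    }
  }
  cfg_l <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg_l$fr_mult <- unlist(cfg_l$fr_mult)
  cfg_l$vt_mult <- unlist(cfg_l$vt_mult)
  known <- names(formals(sim_config))
  extra <- setdiff(names(cfg_l), known)
  if (length(extra)) stop("config.yaml has unknown keys: ",
                          paste(extra, collapse = ", "))
  config <- do.call(sim_config, cfg_l)

  wbp <- utils::read.csv(file.path(dir, "wbp.csv"))
  check_time <- function(tt, file) {
    bad <- which(diff(tt) <= 0)
    if (length(bad)) {
      stop(file, ": time_s not strictly increasing at line ", bad[1L] + 2L)
    }
  }
  check_time(wbp$time_s, "wbp.csv")
  rate <- 1 / stats::median(diff(wbp$time_s))
  trace <- pleth_trace(wbp$pressure, rate = rate,
                       body_mass = config$body_mass,
                       calibration = config$calibration, t0 = wbp$time_s[1L])

  ca <- utils::read.csv(file.path(dir, "ca.csv"))
  check_time(ca$time_s, "ca.csv")
  ca_rate <- 1 / stats::median(diff(ca$time_s))
  rois <- setdiff(names(ca), "time_s")
  if (!length(rois)) stop("ca.csv has no ROI columns")

  pr <- yaml::read_yaml(file.path(dir, "protocol.yaml"))
  ep <- data.frame(co2 = unlist(pr$co2), start = unlist(pr$start),
                   end = unlist(pr$end))
  validate_protocol(ep)
  protocol <- gas_protocol(ep$co2, ep$end - ep$start,
                           analyzer_delay = pr$analyzer_delay %||% 0,
                           t0 = ep$start[1L])
  protocol$start <- ep$start
  protocol$end <- ep$end

  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
  labels <- if (!is.null(truth)) truth$labels else
    data.frame(roi_id = rois, class = NA_character_, qc_defect = NA_character_)

  mv <- NULL
  ef <- file.path(dir, "events.csv")
  events_truth <- if (file.exists(ef)) utils::read.csv(ef) else NULL

  traces <- lapply(rois, function(id) {
    calcium_trace(ca[[id]], rate = ca_rate, roi_id = id, t0 = ca$time_s[1L],
                  check_rate = FALSE)
  })
  out <- list(
    wbp = trace, movement_channel = NULL, protocol = protocol,
    traces = traces,
    truth = list(labels = labels,
                 events = if (!is.null(truth)) truth$events,
                 behavior = list(events = events_truth)),
    config = config
  )
  class(out) <- "ca_dataset"
  out
}
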