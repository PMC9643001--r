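Package: capnotrace
Title: Calcium-Imaging and Plethysmography Analytics for Brainstem
    Chemosensory Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for paired miniscope calcium-fluorescence
    ROI traces and whole-body plethysmography recordings from freely moving
    mice during stepped hypercapnia. Segments breaths and derives tidal
    volume, respiratory frequency and minute ventilation; detects sniff
    bouts, active expiration and movement artefacts; conditions fluorescence
    traces (F/F0, background subtraction, transient detection and kinetics,
    four-criterion quality control); classifies neurons into eight
    chemosensory response classes using protocol-aligned epoch statistics
    and a two-component (3% vs 6% CO2 response) analysis; and performs
    event-triggered averaging, onset-latency and calcium-ventilation
    correlation analyses. Ships a synthetic-data generator that emulates
    the statistical structure of such recordings with ground-truth labels,
    so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
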