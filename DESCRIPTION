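Package: crowdcp
Title: Crowdsourced Consensus Change-Point Labels for EHR Data-Quality Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds data-quality time series (completeness, conformance,
    plausibility) from typed electronic health record extracts at daily,
    weekly and monthly granularity; renders them as fixed-geometry images
    for visual change-point annotation; cleans crowdsourced annotation
    lines (first-attempt filtering, per-person merging with colour
    promotion); derives consensus change-point labels by one-dimensional
    density-based clustering with noise; and evaluates label accuracy
    against expert annotations with an interval-based binary-classifier
    approximation, Wilson confidence intervals, and Matthews correlation
    coefficient grid-search tuning. Includes a synthetic-data generator
    that injects known change points (level, trend, variability,
    presence/absence, outliers) and simulates volunteer annotation
    behaviour so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    lubridate,
    readr,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
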