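Package: photofret
Title: FRET Biosensor Fibre-Photometry Analysis and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for in vivo fibre-photometry recordings of a
    FRET-based calpain-activity biosensor: parses frame-level recordings with
    interleaved LED-off control frames, computes session FRET by interleaved
    control subtraction, expresses drug responses as percent change from the
    pre-treatment baseline (delta-FRET), summarises recording days by maximum
    and minimum delta-FRET and trapezoidal area under the curve, and runs the
    cohort statistics layer (repeated-measures two-way ANOVA with a
    mixed-effects fallback, one-way ANOVA with Tukey post hoc tests, t-tests,
    Pearson correlation, histology-based animal exclusion). Includes a
    mechanistic synthetic-session generator (sensor synthesis and cleavage
    kinetics, drug pharmacodynamics, photobleaching, motion artifacts, camera
    noise) with closed-form oracles, and immunoblot densitometry helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    zip
Suggests:
    readxl,
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
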