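Package: screenfunnel
Title: Staged Hit Calling for Luciferase Reporter Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for multi-stage small-molecule reporter
    screens in 384-well format: plate input/output and layout assignment,
    blank correction, per-plate DMSO-median fold-change normalisation,
    robust Z-prime and signal-to-background plate quality control,
    control-derived activation thresholds, four-parameter logistic
    dose-response fitting with minimal-effective-concentration inversion,
    cytotoxicity counter-screen gating, and comparative delta-delta-Ct
    expression signatures. Includes a synthetic screen generator with
    planted ground truth so the complete funnel can be exercised and
    validated without wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
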