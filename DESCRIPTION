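Package: qitscreen
Title: Kinetic Analysis for Quantitative Irreversible Tethering Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for quantitative irreversible tethering (qIT)
    covalent-fragment screens. Simulates or ingests fluorogenic
    thiol-consumption time courses, normalizes them against DMSO controls,
    fits pseudo-first-order rate constants by exponential regression with
    half-life-based quality gating, computes rate enhancement factors (REF =
    k_protein / k_GSH) against a glutathione control, calls accelerated and
    retarded hits at fixed or FDR-derived thresholds, and quantifies assay
    robustness with time-resolved Z' factors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
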