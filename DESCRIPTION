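Package: clquant
Title: Quantification of Intracellular Chloride Imaging and
    Chloride-Dependent Avoidance Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for quantitative analysis of
    intracellular chloride in sensory neurons from fluorescence-quenching
    (MQAE) imaging: per-cell Stern-Volmer calibration from double-ionophore
    steady states, conversion of resting fluorescence to chloride
    concentration, Nernst-equation predictions of the chloride reversal
    potential and the critical intracellular concentration for efflux,
    k-sigma classification of stimulus-evoked fluorescence responses,
    Fura-2 ratio and amplitude extraction, Hill-equation dose-response
    fitting (EC50/IC50), and brief-access drinking avoidance analysis via
    the Exposure Intake Ratio. A seeded synthetic-data generator emulates
    calibration traces, stimulation traces, ratiometric calcium traces and
    drinking sessions with known ground truth so every stage is testable
    by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
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
    withr
Config/testthat/edition: 3
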