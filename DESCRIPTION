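Package: cpforage
Title: Biologging Analysis of Central-Place Foraging Consistency
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end analysis of GPS and time-depth-recorder data from
    central-place foraging marine predators. Detects and classifies dives
    (benthic versus pelagic via a bimodal bottom-time-weighted depth index),
    filters and segments tracks into foraging trips, computes kernel
    utilization distributions of dive time and a Bhattacharyya-affinity
    Foraging Site Fidelity Index, derives per-trip foraging success and
    efficiency indices from prey-capture probability models, and estimates
    between- versus within-individual repeatability of foraging behaviours
    with mixed models, permutation tests and parametric bootstrap. Includes
    a synthetic-data generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    geosphere,
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
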