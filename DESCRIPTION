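Package: netscreen
Title: Network-Guided RNAi Screen Analysis for Cell Cycle Regulators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for network-guided RNAi screening: builds bait-centric
    protein-interaction maps from edge lists and filters them (hub-bait
    partner removal with multi-study and designated-bait rescue, confidence
    thresholds), tests whether gene sets are more interconnected than
    degree-matched random sets (within-group edge counts and largest
    connected component, permutation nulls), normalizes plate-based
    flow-cytometry cell-cycle profiles (global/plate-mean scaling), calls
    hits in control-SD units, compares screens on a common gene universe,
    applies second-reagent matching-phenotype validation, and assembles
    high-confidence regulator sets. Includes a synthetic-data generator
    with known ground truth for end-to-end calibration of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
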