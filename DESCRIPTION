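Package: focalnet
Title: Association Networks and Origin Effects from Focal-Follow Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Social network analysis for focal-follow observation data on
    group-living animals. Implements the per-day one-zero sampling
    reduction, twice-weight (and half-weight, simple-ratio) association
    indices, weighted per-individual network metrics (strength,
    eigenvector centrality, reach, clustering, affinity), node-label
    permutation tests with Bonferroni-Holm correction, Poisson party-size
    models with observation-effort offsets, two-part (hurdle) models for
    dyadic association indices, and a synthetic focal-follow generator
    with known ground truth for calibration, power, and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
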