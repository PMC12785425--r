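Package: crsnet
Title: Behavioral Emotionality and Marker Co-Expression Network Analysis
    for Chronic Restraint Stress Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for graded chronic restraint stress (CRS)
    mouse cohorts profiled on an 11-marker prefrontal-cortex panel
    (GABAergic, synaptic and astroglial compartments) alongside weekly
    behavioral testing. Implements quantification normalization
    (total-protein Western blot, geometric-mean reference qPCR),
    Grubbs outlier screening and group-mean imputation; behavioral
    readouts including PhenoTyper residual avoidance and the integrated
    Z-emotionality score; marker-behavior correlation and PCA analyses
    with Benjamini-Hochberg correction; per-group co-expression networks
    with hierarchical module detection, Monte-Carlo module-preservation
    testing and Fisher p-value meta-analysis; and Kleinberg hub-score
    centrality with permutation nulls and Stouffer compartment-level
    meta-analysis. A seeded synthetic-cohort generator reproduces the
    study design (6 stress durations x 2 sexes x 8 animals) for testing
    and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
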