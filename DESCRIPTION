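Package: moaplate
Title: Plate-Based In Vitro Metabolomics for Hepatotoxicity Mode-of-Action Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis workflow for 96-well HepG2 metabolomics
    screens: dose selection from three-parameter Weibull (W1.3) ATP
    dose-response fits, per-metabolite quality-control gating (coverage,
    blank contribution, linearity, variability), two-tier normalization
    (same-plate reference-sample ratios followed by within-sample median
    scaling), Welch-test differential profiling with ontology-class
    enrichment, PCA and bootstrapped hierarchical clustering of treatment
    profiles, and derivation of mode-of-action metabolite fingerprints with
    nearest-centroid classification of new compounds. Includes a synthetic
    plate-data generator that emulates the experimental design (interior-well
    layouts, lyophilized reference samples, log-normal technical and
    biological noise, batch and cell-number factors, planted effect
    signatures) so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    rlang,
    withr,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
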