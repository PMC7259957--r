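Package: ercal
Title: Luminal Calcium Regulation of the InsP3 Receptor: Enrichment,
    Gating and Imaging Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipelines for studying endoplasmic-reticulum luminal
    calcium regulation of the inositol 1,4,5-trisphosphate receptor
    (InsP3R). Implements a hierarchical Poisson log-linear model with a
    spike-and-slab prior and local-false-sign-rate inference for
    bait-versus-control spectral counts from affinity-enrichment mass
    spectrometry; idealization and gating statistics (open probability,
    dwell times, active-channel counting with a confidence rule,
    current-voltage ramp fits) for single-channel patch-clamp records;
    nonlinear least-squares fitting of the inhibitory Hill equation for
    luminal-calcium suppression of channel open probability; and
    classification and kinetic fitting of single-cell ratiometric calcium
    imaging traces. Every stage ships with a seeded synthetic-data
    generator matching the statistical structure the analysis assumes, so
    the full workflow is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
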