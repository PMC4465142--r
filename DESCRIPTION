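Package: gatedvh
Title: DVH Metrics, Relative Seriality NTCP and Paired Cohort Comparison
    for Breathing-Adapted Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing free-breathing and inspiration-gated
    radiotherapy plans from dose-volume histograms (DVHs). Provides
    differential and cumulative DVH containers with the standard dose and
    volume metrics (mean dose, near-maximum dose D2%, VxGy, relative
    coverage), the relative seriality normal tissue complication
    probability (NTCP) model with a Poisson dose-response and published
    parameter sets for cardiac mortality and radiation pneumonitis, the
    maximum heart distance statistic on a beam's-eye-view scene, paired
    and unpaired two-sided Wilcoxon comparisons with exact small-sample
    p-values, and a seeded generator of paired synthetic DVH cohorts for
    testing the full pipeline without planning-system exports.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
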