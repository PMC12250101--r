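Package: gingicol
Title: Quantitative Analysis of Gingival Colour Change in CIELAB Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying gingival colour and its change with
    inflammation and periodontal treatment from spectrophotometric CIELAB
    measurements. Implements the Euclidean (dEab) and CIEDE2000 (dE00)
    colour-difference formulas with gingiva-specific 50:50% perceptibility
    thresholds, the clinical aggregation rules turning site-level plaque and
    Loe-Silness gingival-index scores into analysis groups, paired and
    unpaired comparisons with Cohen's d effect sizes, exhaustive
    cross-biotype pairing, and pre/post treatment summaries. A seeded
    synthetic-cohort generator, calibrated to published group means and
    standard deviations, makes every pipeline stage testable without
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
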