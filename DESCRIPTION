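Package: riboquant
Title: Quantification of In Situ Hybridization Dots and Cell
    Type-Specific qPCR Fold Changes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for two quantification workflows used in cell
    type-resolved studies of transcript abundance in brain tissue.
    The imaging half implements a semi-automated fluorescence in situ
    hybridization (smFISH/RNAScope-style) protocol: non-local means
    denoising, adaptive local thresholding into connected components,
    partition of anatomical regions into parvalbumin-positive and
    -negative regions of interest, background-corrected estimation of
    single-dot intensity and total dot number, co-expression overlap
    metrics, and per-cell intensity distributions. The qPCR half
    implements reference-gene stability selection (model-based
    variance decomposition and pairwise-M style measures with rank
    aggregation), countervailing-pair selection, delta-delta-CT fold
    changes with first-order error propagation, marker enrichment
    tests, Welch group tests and step-down Sidak multiplicity
    correction. A synthetic-data module generates ground-truthed
    images, CT tables and sleep-score series so every stage is
    testable end to end, and a sleep-behavior exclusion screen is
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tiff,
    png,
    yaml,
    jsonlite,
    EBImage
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
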