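Package: ramanome
Title: Single-Cell Raman Spectroscopy Stress-Response Profiling
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for treating the collection of single-cell Raman spectra
    (SCRS) from an isogenic population as a multiplex phenotype ("ramanome").
    Provides readers and writers for wide-format spectral tables, spectral
    preprocessing (cropping, asymmetric-least-squares baseline removal,
    resampling, normalization, SNR-based quality control), a synthetic-spectra
    simulator with configurable stressor signatures, permutation ANOSIM,
    per-band Wilcoxon tests with D-values, Random-Forest and PC-LDA
    classification, NIPALS partial-least-squares calibration of per-cell
    metabolite density, temporal marker-band clustering, signed Raman
    barcodes (RBCS) with mechanism-based stressor clustering, and per-band
    relative-standard-deviation heterogeneity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    cluster,
    ranger,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
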