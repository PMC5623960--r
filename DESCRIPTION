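Package: persealip
Title: Untargeted LC-MS Lipidomics and Targeted Acetogenin Quantification
    for Avocado Tissues
Version: 0.1.0
Authors@R:
    person("persealip", "maintainers", email = "persealip@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of an LC-MS lipidomics pipeline for
    avocado (Persea americana) mesocarp, idioblast and seed tissue: synthetic
    ESI-TOF scan-map and ground-truth generation, windowed-quantile 2D
    baseline correction, grid-based chromatographic peak detection, isotope
    grouping, RANSAC retention-time alignment, gap filling, co-elution
    grouping by intensity correlation, adduct enumeration and lipid-database
    annotation with hierarchical class-composition weighting, targeted
    calibration-curve quantification of aliphatic acetogenins and fatty
    acids, and downstream statistics (quantile normalization, PCA,
    divergent-group selection, LOWESS trends, Tukey HSD letters, signed
    fifth-power correlation heatmaps, and power-law dry-weight models).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    igraph,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
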