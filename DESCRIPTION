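Package: timescape
Title: Spatial Analysis of the Tumor Immune Microenvironment from
    Multiplex Imaging Cell Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the spatial immune landscape of tumors
    from cell-level multiplex imaging data (imaging mass cytometry or multiplex
    immunofluorescence). Provides intensity-threshold cell phenotyping and
    H-score quantification, inflammatory cellular-neighborhood assignment
    around marker-combination-positive anchor cells, cross-type
    nearest-neighbor distance (G-cross) estimation with border correction and
    AUC summaries, beta-regression comparison of compositional features
    between cohorts with Benjamini-Hochberg false discovery rate control, and
    Kaplan-Meier / cluster-robust Cox proportional-hazards models linking
    spatial features to survival. Includes a synthetic-cohort generator with
    known spatial, compositional, and survival ground truth for validation,
    and a config-driven end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
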