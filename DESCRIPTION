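Package: histotype
Title: Protein-Based Subtyping of Urothelial Carcinoma and Weakly
    Supervised Prediction from Histology Slides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assigns luminal, basal and indifferent protein-based subtypes
    of upper-tract urothelial carcinoma from immunohistochemical H-scores
    by core aggregation, per-marker standardization and Ward hierarchical
    clustering, and predicts the luminal/basal subtype directly from
    annotated H&E slide images through a weakly supervised tile
    classifier.  Includes slide tessellation with quality control and
    Macenko stain normalization, patient-level repeated cross-validation
    with class balancing, slide-level aggregation of tile predictions
    with confidence banding, tile-grid prediction maps with connected
    component heterogeneity detection, evaluation metrics with Student-t
    fold confidence intervals, exact association tests, and a seeded
    synthetic-data generator (H-score cohorts and textured pseudo-slides)
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
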