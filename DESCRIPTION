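Package: gliotile
Title: Tile-Based Semi-Supervised Classification of Glioma Subtypes in Histology Slides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for whole-slide-image tile classification of
    adult-type diffuse glioma subtypes (astrocytoma, oligodendroglioma,
    glioblastoma) against normal brain tissue and necrosis. Provides
    overlapping-tile extraction from rectangular region-of-interest
    annotations, dihedral (D4) augmentation, per-channel normalization,
    class-weighted cross-entropy training with best-epoch selection, a
    two-step semi-supervised procedure that pseudo-labels unannotated tiles
    under a confidence gate and a slide-diagnosis consistency filter,
    macro-averaged multiclass evaluation, and slide-level probability
    heatmaps. Includes a seeded synthetic H&E-like cohort generator with
    controllable class separability for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    tiff,
    MASS,
    optparse
Config/testthat/edition: 3
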