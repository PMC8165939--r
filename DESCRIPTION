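Package: deltasphere
Title: Frame-to-Frame Delta Segmentation and Phenotype Profiling of Live
    Spheroid Time-Lapse Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for phase-contrast time-lapse imaging of
    3D spheroid cultures in multi-well plates. Segments moving spheroids by
    subtracting consecutive frames (Delta images), so that static background
    and optical halo artifacts cancel; measures per-timepoint morphological
    features (area, perimeter, form factor, moment-ellipse axes); profiles
    the divergence of culture conditions over time with principal component
    analysis; and trains a small convolutional network to classify spheroid
    phenotype (round, self-renewing versus branched, differentiating) from
    centroid-cropped images, with strict well-level train/evaluation splits.
    Includes a synthetic phantom generator producing ground-truthed round and
    branched spheroid series so the whole pipeline is testable without
    microscopy data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    cluster,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
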