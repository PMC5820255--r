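Package: cranioshape
Title: Cranial Shape Comparison with Curvature Maps for Craniosynostosis Surgery Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An objective, user-independent pipeline for comparing infant
    skull shapes, aimed at pre-operative planning of open cranial vault
    reconstruction in craniosynostosis. Cranial CT volumes (or synthetic
    phantoms generated in-package) are segmented at a bone threshold,
    iso-surfaced to triangle meshes, placed in a canonical skull-base
    coordinate frame from four anatomical landmarks, and resampled by
    raycasting onto a fixed hemi-icosphere direction set so that skulls
    become directly comparable and averageable into age-group reference
    skulls. Per-vertex Gaussian curvature is estimated by area-weighted
    implicit quadric fitting at a metric scale and log-compressed as a
    signed spherical radius; ring-neighbourhood curvature maps are compared
    by L1 distance to locate the region on a patient skull whose shape best
    corresponds to a chosen reference area.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp (>= 1.0.0),
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
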