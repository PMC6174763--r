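Package: thyrosweep
Title: Classical Segmentation of Tracked Freehand 3D Thyroid Ultrasound Sweeps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation toolkit for tracked (freehand 3D) thyroid
    ultrasound sweeps. Implements four classical segmenters - Chan-Vese
    active contours without edges with tracking-matrix propagation of the
    initialization across slices, GrabCut-style iterative graph cut with
    Gaussian mixture colour models and scribble interpolation, a
    decision-tree pixel classifier on local texture features, and a
    random-forest voxel classifier - together with Dice and Hausdorff
    evaluation, sweep-to-volume reconstruction by inter-frame signed
    distance interpolation, thyroid volume computation, and a synthetic
    speckle phantom with exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    ranger,
    rpart,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
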