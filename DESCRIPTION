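Package: forestseg
Title: Individual Tree Instance Segmentation for Leaf-Off Forest Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end instance segmentation of individual trees in leaf-off
    forest point clouds. Provides point-cloud input/output (PLY, LAS, XYZ),
    a procedural generator of labelled leaf-off plantation plots, the
    preprocessing chain (statistical outlier removal, ground classification,
    DEM height normalization, class balancing, sliding-window tiling), a
    sparse voxel convolutional U-Net with global-context channel attention,
    a set-prediction mask decoder whose mask scores combine query-feature
    similarity with a distance penalty to predicted instance centers, and
    the standard semantic and instance segmentation metrics (precision,
    recall, F1, IoU, AP, AP50, AP25, mPrec, mRec, mCov, mWCov). Training runs
    on a built-in reverse-mode automatic differentiation engine, so the whole
    pipeline is exercisable on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
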