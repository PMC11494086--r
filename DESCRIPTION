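Package: smpdiou
Title: Angle-Adaptive Bounding-Box Regression Losses, Multi-Dimensional
    Attention, and Slide Patch Triage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the complete IoU-based bounding-box regression
    metric family (IoU, GIoU, DIoU, CIoU, EIoU, SIoU, MPDIoU) together
    with S-MPDIoU, an angle-adaptive variant whose corner-distance
    penalty is normalised by a baseline chosen from the angle between
    the box centers and amplified by a feature-map scale factor. Every
    metric is exposed both as a similarity and as a differentiable loss
    with analytic gradients, and a vectorised gradient-descent simulator
    measures convergence behaviour of the whole family on fixed and
    randomised box-regression populations. Also provides the
    Multi-Dimensional Attention (MDA) operator - channel attention via
    spatial pooling and adaptive one-dimensional convolution followed by
    width- and height-direction attention - and a desk-scale
    whole-slide-image patch triage pipeline (background filtering,
    fixed-size tiling, pluggable per-patch cell counting, threshold
    flagging, overlay rendering) exercised on synthetic slides.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, Classification, CellBiology
RoxygenNote: 7.3.3
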