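Package: rootvoid
Title: Small-Void Detection in Root-Canal Radiographs with Residual
    Convolution, Token Attention, and a Combined IoU Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A compact, fully self-contained object-detection toolkit for
    locating small voids in radiographs of obturated root canals.  Implements
    a residual convolution block that carries the standard-convolution output
    past a depthwise stage, a tokenized self-attention block that restricts
    attention to non-overlapping spatial tokens, and a combined bounding-box
    regression loss that augments complete-IoU with corner-distance penalties
    so that disjoint boxes still receive a useful gradient.  Includes a
    scaled-down anchor-free detector with FPN/PAN feature fusion trained by
    hand-written backpropagation on the CPU, from-scratch precision/recall and
    mAP evaluation, a synthetic radiograph phantom generator with YOLO-format
    label input/output, mosaic augmentation, and letterbox resizing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
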