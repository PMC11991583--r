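Package: LGWheatNet
Title: Lightweight Multi-Scale Wheat Spike Detection and Counting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lightweight convolutional detector for wheat spikes in field
    images across three growth stages (flowering, grain filling, maturity).
    Implements the SeCUIB inverted-bottleneck block with squeeze-excitation
    attention and channel shuffle, the DWDown depthwise downsampling module,
    SPPF pooling and the grouped/depthwise LightDetect head, assembled into a
    MobileNetV4-small style backbone with an FPN+PAN neck. Provides the CIoU
    box loss with task-aligned target assignment, SGD training with warmup and
    linear decay, VOC-format dataset input/output with an offline augmentation
    suite, detection and counting metrics, sliced (SAHI-style) inference for
    large images, a synthetic wheat-canopy scene generator for fully offline
    testing, and an ablation harness reporting parameter and GFLOP counts per
    architecture variant.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    xml2,
    png,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
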