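Package: dfcn
Title: Dilated Fully Convolutional Networks for Multi-Organ Chest CT
    Segmentation
Version: 0.1.0
Authors@R:
    person("dfcn", "maintainers", email = "dfcn@example.org", role = c("aut", "cre"))
Description: Training, evaluation and synthetic benchmarking of dilated
    (atrous) fully convolutional networks for automated delineation of
    thoracic organs at risk on axial chest CT. Provides a Hounsfield-unit
    window-adjustment input layer that maps one CT channel onto three
    equally partitioned display windows, construction of the VGG16-based
    FCN 32s/16s/8s family and its dilated D-FCN 16s/8s/4s derivatives via
    stride removal with dilation compensation, a CPU forward/backward
    engine, Dice similarity metrics (per structure and global), an
    iterative training harness with checkpointing and Dice-curve based
    model selection, a parametric thoracic CT phantom generator, NIfTI-1
    input/output, mask-to-contour extraction, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
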