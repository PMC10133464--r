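Package: dsseg
Title: Dual-Student Adversarial Domain Adaptation for Image Segmentation
Version: 0.1.0
Authors@R:
    person("dsseg", "maintainers", email = "dsseg@example.org", role = c("aut", "cre"))
Description: Unsupervised domain adaptation for semantic segmentation built
    around a pair of independently initialized student segmentation networks.
    The students are coupled only through a reliability-gated cross-coordination
    consistency constraint on unlabeled target-domain data, and each student is
    aligned across domains by its own adversarial discriminator. Includes a
    compact U-Net segmentor and fully convolutional discriminator with
    hand-written gradients (CPU-scale), compound dice/cross-entropy supervised
    losses, transform-consistency regularization, training loops for the
    proposed method and standard baseline arms (mean teacher, entropy
    minimization, adversarial-only, dual student), a synthetic nested-lesion
    phantom generator with controllable domain shift, and dice/Hausdorff
    evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
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
RoxygenNote: 7.3.3
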