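Package: hmtnet
Title: Hierarchical Multi-Task Networks for Diabetes Screening from
    Conjunctival Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains and evaluates hierarchical multi-task convolutional
    networks (HMT-Net) that detect a systemic disease signal from
    ocular-surface images. Expert-designed sub-question classifiers
    (vessel widening, perivascular color, tortuosity, microaneurysms)
    are trained first, then frozen and fused through channel attention
    and two compression convolutions into a final disease classifier.
    Includes a synthetic conjunctiva image generator with ground-truth
    lesion masks, a manifest/quality-filter/augmentation data pipeline,
    a two-stage training protocol with fivefold cross-validation,
    confusion-matrix and ROC/AUC evaluation, and class activation maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    png,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
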