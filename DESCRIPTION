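Package: neosono
Title: Quantitative Echogenicity Grading of Neonatal Cranial Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-stage grading of hypoxic-ischemic brain injury on neonatal
    cranial ultrasound images. Stage one quantifies the echogenicity
    difference between a choroid-plexus and a brain-parenchyma region of
    interest as the Delta E (CIE76) distance between region-mean CIE Lab
    coordinates, categorized against clinical thresholds into Normal,
    Moderate and Intensive grades. Stage two classifies two-region composite
    images with a compact convolutional network (conv/batch-norm/ReLU/max-pool
    blocks, RMSProp training). The package also provides a speckle phantom
    generator for fully synthetic, label-controlled datasets, stratified
    splitting and k-fold cross-validation, a one-vs-rest evaluation suite
    (confusion matrix, sensitivity, specificity, precision, accuracy,
    F-measure, ROC AUC, macro summaries), and paired before/after clinical
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    jsonlite,
    yaml,
    EBImage,
    e1071,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
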