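Package: mipanomaly
Title: Explainable One-Class Anomaly Detection for Breast MRI Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for explainable cancer screening on breast MRI
    maximum-intensity projections (MIPs) using fully convolutional data
    description (FCDD) anomaly detection.  Provides a synthetic bilateral
    breast-phantom generator with pixel-level truth masks, subtraction-MIP
    preprocessing, a small fully convolutional backbone trained with the
    pseudo-Huber hypersphere (FCDD / HSC) and binary cross-entropy
    objectives, receptive-field Gaussian upsampling of anomaly heat maps,
    Grad-CAM saliency for the comparator models, pixelwise-AUC
    explainability scoring against truth masks, and an imbalanced screening
    evaluation protocol (patient-grouped cross-validation, AUC / AUPR with
    prevalence baselines, Youden and fixed-sensitivity operating points,
    bootstrap confidence intervals and paired Wilcoxon tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
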