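Package: mlcqa
Title: Characterisation of Multileaf Collimator Position Errors from Dose-Distribution Indices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates segmented-MLC IMRT plans and dose distributions on
    TG-119-like phantom geometries, injects systematic and random multileaf
    collimator (MLC) leaf-position errors, and characterises the resulting
    dose differences with local gamma analysis, the structural similarity
    (SSIM) index and its luminance/contrast/structure subcomponents, and a
    34-feature dosiomics vector (GLCM, GLRLM, NGLDM, GLZLM textures)
    extracted from subtracted dose maps. Significant indices are screened by
    Spearman correlation with Holm-Bonferroni correction, backward stepwise
    elimination and variance-inflation filtering, and logistic-regression
    error classifiers are trained with repeated 10-fold cross-validation and
    gated on held-out accuracy, precision, sensitivity and specificity.
    Dose-volume-histogram differences quantify the clinical impact.
    Includes a minimal DICOM-RT Plan/Dose reader and writer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    caret,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    car,
    glmnet,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
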