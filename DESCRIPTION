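Package: radsig
Title: Multiregional Radiomic Signatures from DCE-MRI Parametric Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for building intratumoral, peritumoral and
    multiregional radiomic signatures of hormone-receptor status from
    dynamic contrast-enhanced breast MRI. Computes six semi-quantitative
    kinetic parametric maps (MSI, SI-slope, E-initial, ESER, E-peak, SEP)
    from a 9-frame time series, segments the lesion by between-class-variance
    thresholding of subtraction images, derives a 4 mm peritumoral ring
    constrained to the breast mask, extracts a 4980-feature bank
    (first-order, GLCM, Laws, Gabor) per case, and selects features by an
    ICC reproducibility filter, two-sample t-tests, cross-validated LASSO
    and backward stepwise AIC before fitting logistic rad-score models
    evaluated by ROC analysis. Includes a seeded synthetic DCE cohort
    generator with class-dependent enhancement kinetics for testing every
    stage without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    glmnet,
    pROC,
    stats,
    utils,
    jsonlite,
    yaml,
    rlang,
    RNifti,
    png
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
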