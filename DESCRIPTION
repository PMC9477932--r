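Package: fetrad
Title: Static FET PET Radiomics for Differentiating Glioma Progression
    from Treatment-Related Changes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for static amino-acid (FET) PET radiomics:
    standardized-uptake-value conversion, scanner-harmonization smoothing,
    two-dimensional threshold auto-contour lesion segmentation at a
    tumor-to-brain ratio of 1.6, TBR quantification, extraction of fractal,
    first-order, shape, gray-level texture (GLCM/GLRLM/GLSZM) and
    wavelet-domain features, a three-stage feature-selection cascade
    (near-zero variance, pairwise correlation, forward selection under
    cross-validated AUC), logistic-regression classifiers, and ROC
    evaluation with DeLong confidence intervals.  A seeded phantom and
    cohort generator emulates the statistical structure of a two-class
    (tumor progression vs. treatment-related changes) FET PET study so
    that every stage is verifiable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
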