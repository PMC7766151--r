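Package: fetrad
Title: FET PET Radiomics and Conventional Parameters for Pseudoprogression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis workflow for differentiating pseudoprogression from
    early tumor progression after chemoradiation in glioma using dynamic
    O-(2-[18F]fluoroethyl)-L-tyrosine (FET) PET. Provides a digital
    dynamic-PET phantom with two kinetic classes, tumor-to-brain-ratio
    iso-contour segmentation with three-threshold augmentation,
    conventional static and dynamic parameters (TBRmean, TBRmax,
    time-to-peak, late-window slope), a from-scratch 3D radiomics engine
    (944 features on original, Laplacian-of-Gaussian and coif1 wavelet
    images), ROC and cut-off statistics with combination rules,
    Kaplan-Meier survival comparison, and a recursive-feature-elimination
    random-forest classification pipeline with patient-grouped validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    survival,
    randomForest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
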