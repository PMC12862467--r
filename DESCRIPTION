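Package: omrad
Title: Optimal-Margin-Region Radiomics for Peritumoral Texture Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for margin-band radiomics of 3D lesions on scalar image
    volumes. Generates parameterized inner/outer margin-band volumes of
    interest around a binary lesion mask, computes a curated set of
    first-order, shape, gray-level co-occurrence (GLCM) and neighbourhood
    gray-tone difference (NGTDM) texture features under logarithm,
    Laplacian-of-Gaussian and stationary-wavelet intensity filters, runs a
    feature-selection-chain by margin-region model-selection grid ranked by
    internal-test AUC, and stratifies patients at the maximum-Youden cutoff
    with Kaplan-Meier/log-rank survival and contingency-table association
    analyses. Includes a deterministic phantom-cohort simulator with a
    planted margin-band texture effect for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    glmnet,
    MASS,
    survival,
    randomForest,
    xgboost,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
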