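Package: fibrograph
Title: Lung-Graph Radiomics Pipeline for Fibrotic Interstitial Lung Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end machine-learning pipeline that discriminates fibrotic
    from non-fibrotic interstitial lung disease on 3D CT volumes. The lung
    fields are partitioned into a 36-region geometric atlas; 1004 radiomics
    features (first-order, shape, GLCM, GLRLM, GLSZM, NGTDM, GLDM over 11
    filtered image types) are computed per region; each feature defines a
    regional "lung graph" summarised by ten order and moment statistics into
    a 10040-element descriptor; two-step Mann-Whitney/Pearson feature
    selection feeds a cross-validated classifier zoo with a greedy weighted
    ensemble, evaluated at scan and patient level with bootstrap confidence
    intervals and DeLong tests. Includes a seeded synthetic chest-phantom
    generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    nnet,
    glmnet,
    e1071,
    ranger,
    xgboost
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
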