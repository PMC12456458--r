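Package: clusso
Title: Clustering Structured Lasso for Scalar-on-Matrix Regression with
    Unbalanced Feature Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scalar-on-matrix regression for subjects whose matrix-valued
    predictors (e.g., per-tubule digital-pathology image features) have
    differing, unordered numbers of rows. Pooled objects are clustered into
    latent subgroups, per-subject cluster-averaged and proportion-weighted
    design matrices are formed, and a constrained bilinear ("structured")
    lasso with row effects alpha (constrained to unit L1 norm) and
    L1-penalized column effects beta is fit by alternating minimization.
    Includes the Full Information oracle fit from known subgroup labels, a
    naive averaging lasso baseline, cross-validated regularization, an L1
    coefficient estimation error bound, synthetic data generators for the
    supported simulation scenarios, and a replication harness computing
    selection and prediction performance metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    graphics,
    jsonlite,
    mclust,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
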