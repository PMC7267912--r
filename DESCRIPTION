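Package: icsearch
Title: Information Cluster Search for Voxel-Level Brain Information Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Data-driven multivariate information mapping of functional brain
    images at voxel resolution. Implements the information cluster search (ICS)
    algorithm: a greedy expand/prune traversal of the voxel grid guided by a
    spectral trace-ratio relevance score (between- over within-class scatter of
    subject affinity graphs) and a mutual-information redundancy pruner, with a
    memoized search engine. Includes a synthetic BOLD data generator with
    spatially correlated noise and planted condition-specific patterns, a
    searchlight baseline sharing the same spectral score, an L1-regularized
    linear baseline, cross-validated AUC scoring of discovered clusters, and
    detection metrics against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    glmnet,
    e1071,
    RNifti,
    jsonlite,
    readr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
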