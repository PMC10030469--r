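Package: coupleseg
Title: Iterative K-Means and Lasso Segmentation of Couple Survey Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Audience segmentation of couple-level survey populations for
    targeting direct-to-beneficiary mobile health programmes. Implements
    an iterative procedure that alternates K-Means clustering with
    L1-regularised (Lasso) selection of survey variables against a
    strong-signal prevalence score, together with cluster-validity
    indices (within-cluster sum of squares, silhouette, Calinski-Harabasz
    and Ray-Turi), elbow selection of the number of clusters,
    differential programme-impact tables by cluster and exposure arm, and
    a synthetic couple-survey generator with planted cluster structure
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
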