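Package: pairtarget
Title: Shared-Target Prediction for Small-Molecule Pairs by Similarity Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts whether two small molecules share a protein target by
    fusing seven fingerprint Tanimoto similarities, maximum common
    substructure statistics, and per-molecule physicochemical descriptors
    into pairwise feature vectors, training class-weighted regularized
    logistic regression, naive Bayes, and tuned random forest classifiers
    on drug-disjoint splits, and screening query compound libraries against
    reference drug libraries with a multi-model consensus hit call. Also
    provides the fluorescence-kinetics slope and percent relative
    inhibition arithmetic used for enzymatic follow-up assays, and a
    synthetic scaffold-family library generator for hermetic end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    Rcpp,
    glmnet,
    ranger,
    e1071,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    igraph,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
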