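Package: screenflow
Title: Semi-Automated Title/Abstract Screening for Knowledge Syntheses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A semi-automated, human-in-the-loop workflow for title and
    abstract screening in systematic and scoping reviews. Citations are
    represented three ways (latent semantic vectors from a truncated SVD of
    an n-gram document-feature matrix, topic proportions from latent
    Dirichlet allocation over nouns and verbs, and frequency-weighted
    average word embeddings), a training set is grown from a handful of
    eligible seed abstracts by k-nearest-neighbour expansion over the three
    distance measures (cosine and word-mover distance), and a
    SMOTE-rebalanced random forest tuned by cross-validation to maximise
    sensitivity is iterated with reviewer confirmation until no new
    eligible abstracts are found. Includes evaluation against a reference
    standard (sensitivity, precision, F1, specificity, accuracy, workload
    reduction and person-hours saved) and a synthetic-corpus generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    Rcpp,
    ranger,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
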