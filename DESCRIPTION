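Package: notesieve
Title: Weakly Supervised Relevance Filtering for Clinical Note Corpora
Version: 0.1.0
Authors@R:
    person("Alex", "Doran", email = "alex.doran@example.org", role = c("aut", "cre"))
Description: Tools for deciding which clinical notes in a large electronic
    health record corpus are relevant to a condition of interest, built around
    weak supervision. Diagnosis-code and timing heuristics over encounter
    metadata generate silver-standard training labels; classifiers (random
    forest, gradient boosted trees, k-nearest neighbours, and a
    compression-distance k-NN) are trained on five text representations
    (bag of words, TF-IDF, paragraph-vector document embeddings, gzip
    compression features, and lexicon-based concept vectors with assertion
    status); a small gold-annotated set calibrates the decision threshold;
    evaluation reports confusion-matrix metrics with percentile bootstrap
    confidence intervals. A synthetic cohort generator with controllable
    coding noise makes the whole pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    Rcpp,
    digest,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
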