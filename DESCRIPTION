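Package: dilitext
Title: Controlled-Vocabulary Text Classification of Drug-Induced Liver Injury
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Bag-of-words classification of adverse-event risk (drug-induced
    liver injury, DILI) from regulatory free text. Extracts only
    controlled-vocabulary preferred terms (MedDRA-style) from documents via
    longest-match phrase matching with explicit synonym recoding, builds a
    sparse TF-IDF document-term matrix, fits a gradient-boosted tree
    classifier with repeated stratified cross-validation, ranks term
    importance by splits/gain/cover, runs cost-sensitive threshold (profit
    matrix) and probability-decile consistency analyses, and scores new or
    cross-corpus documents with a frozen-IDF saved model. Includes a
    planted-signal synthetic corpus generator and a command-line interface so
    the whole pipeline is testable without licensed dictionaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    tools,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
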