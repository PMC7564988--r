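Package: dialogforge
Title: Automatic Labeled Dialogue Generation for Nursing-Record Natural
    Language Understanding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for bootstrapping natural language understanding (NLU)
    training data for nursing record systems. An ontology of action-driven
    intents and entity slots drives a rule-based utterance augmentation
    engine (phrase shuffling, slot filling, paraphrase transformations)
    that emits a gold-labeled utterance corpus. Skip-gram and subword
    character n-gram word embeddings can be trained on the generated
    corpus, utterances and entity candidates are embedded and clustered
    with k-means (k-means++ initialization) and labeled by per-cluster
    majority vote, and a character-level LSTM language model generates
    novel utterances. Evaluation utilities cover pair-counting
    precision/recall/F1, silhouette coefficients, BLEU, and corpus
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: C++17
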