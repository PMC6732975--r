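Package: emotopics
Title: Gender-Stratified Emotion, Happiness and Topic Analysis of Microblog Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for lexicon-based emotion analysis of
    microblog (tweet) corpora stratified by author gender. Implements
    deterministic text cleaning, NRC-style eight-emotion word counting with a
    per-tweet emotion-proportion statistic compared across groups by a
    variance-ratio test and a Wilcoxon rank-sum test, hedonometer-style word
    happiness scoring of tweets, days and word sets, and a covariate-aware
    topic analysis built on collapsed-Gibbs latent Dirichlet allocation with
    topic-number selection diagnostics, FREX/score word profiles, semantic
    coherence, bootstrap gender-prevalence effects, compositional topic
    correlations and topic happiness comparisons. Ships a synthetic-corpus
    generator with recorded ground truth so every stage is testable without
    any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods,
    rlang,
    dplyr,
    tibble
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
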