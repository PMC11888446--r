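Package: curriculab
Title: Curriculum Learning for Antibody Language Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A desk-scale framework for curriculum pre-training of antibody
    language models on mixtures of unpaired and natively paired heavy/light
    chain sequences. Provides a seeded synthetic repertoire generator,
    ESM-style tokenization with configurable chain-separator policies, the
    sigmoid unpaired-probability schedule with exact calibration of its
    midpoint against a total unpaired data budget, mixed paired/unpaired
    batch planning with masked-language-model collation, a small
    configurable bidirectional transformer encoder with rotary or absolute
    positional embeddings, masked-token evaluation metrics (including
    per-region cross-entropy and CDRH3 accuracy), and construction plus
    cross-validated scoring of native-vs-random pair classification and
    antigen-specificity classification tasks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    pROC,
    Biostrings,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
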