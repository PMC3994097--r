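Package: chatohm
Title: Hybrid Associative Classifiers with One-Hot Output Coding
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Associative-memory classifiers for labeled tabular data: the
    Steinbuch Lernmatrix, the Linear Associator, the hybrid associative
    classifier with axis translation (CHA/CHAT), and CHAT-OHM, which codes
    outputs one-hot per training pattern and classifies by majority voting
    over masking vectors. Includes the surrounding experimental pipeline:
    population z-score normalization, Wilson editing (edited nearest
    neighbour) of atypical patterns, class-conditional mean/mode imputation,
    repeated stratified k-fold cross-validation, CSV/ARFF dataset loading
    with schema configuration, text-based model serialization, synthetic
    data generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    foreign,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
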