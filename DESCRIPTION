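Package: mechknn
Title: Multi-Label Nearest-Neighbour Prediction of Enzyme Catalytic Mechanism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the chemical mechanism of an enzyme (MACiE-style
    mechanism labels, optionally refined with subunit roles) from sequence-derived
    attributes: binary InterPro/CSA signature presence, per-mechanism minimum
    Euclidean distance and maximum global-alignment sequence identity profiles.
    Implements a binary-relevance k-nearest-neighbour multi-label classifier
    (k = 1 by default) with Euclidean or Jaccard distance, an exact-signature
    direct-transfer baseline and a sequence-identity/signature-distance line
    separator, together with leave-one-out, k-fold and train/test evaluation
    drivers, subset accuracy and micro/macro-averaged precision, recall and
    specificity, Mulan-dialect sparse/dense ARFF + label-XML input/output,
    FASTA handling, and a deterministic synthetic protein-family generator
    for end-to-end testing without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    xml2,
    Biostrings
Suggests:
    foreign,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
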