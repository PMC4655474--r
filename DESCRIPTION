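Package: elrmotif
Title: Within-Motif Dependence of Transcription Factor Binding via
    Association Rule Mining and Elastic-Net Logistic Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models transcription factor (TF) binding motifs beyond the
    position-independence assumption of the position weight matrix (PWM).
    Candidate binding sequences are collected by scanning a genome with a
    PWM against a first-order Markov background; frequent itemsets of
    single-base features are mined with the Apriori algorithm and
    positive/negative association rules are derived by confidence and
    phi-correlation thresholds; the integrated association features enter
    an elastic-net regularized logistic regression (ELRM) together with
    sum-to-zero dummy-coded single-base features, trained against a 30-fold
    negative set built from column-permuted PWM hits, GC-matched random
    sequences and low-scoring genomic windows. Selected features yield a
    concise, graphically representable description of the binding
    configuration. Includes a synthetic-data generator that plants motif
    instances with controlled positional dependencies, cross-validation
    and threshold-screening utilities, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    glmnet,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
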