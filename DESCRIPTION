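Package: m6aFuse
Title: Multi-Encoder Deep Learning Prediction of RNA N6-Methyladenosine Sites
Version: 1.0.0
Authors@R:
    person("m6aFuse", "Developers", email = "m6afuse@example.org",
           role = c("aut", "cre"))
Description: Predicts N6-methyladenosine (m6A) modification sites from
    fixed-length, adenine-centered RNA sequence windows.  Eight sequence
    encoders (binary one-hot, tri-nucleotide composition, enhanced nucleic
    acid composition, K-spaced nucleotide pair frequencies, nucleotide
    chemical properties, pseudo dinucleotide composition, and position-specific
    mono- and di-nucleotide propensities) are fused into one feature matrix,
    reduced by elastic-net feature selection, and classified with a
    feed-forward deep neural network whose hyper-parameters can be tuned by a
    native tree-structured Parzen estimator.  Includes a synthetic benchmark
    generator, stratified cross-validation with fold-safe refitting of all
    label-dependent components, the standard binary-classification metric
    suite (Sn, Sp, ACC, MCC, AUC), and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
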