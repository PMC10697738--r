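Package: m6aconv
Title: Single-Nucleotide m6A Site Prediction and Interpretation with
    Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts N6-methyladenosine (m6A) modification sites at
    single-nucleotide resolution from RNA sequence windows using a small
    convolutional neural network over an ENAC (enhanced nucleic acid
    composition) encoding, and interprets trained models through two
    complementary strategies: model-based interpretation (first-layer
    filter motif extraction as position frequency matrices, activated
    amounts, and virtual-pruning impact scores) and propagation-based
    interpretation (in-silico mutagenesis and input-gradient attribution
    maps). Includes benchmark-dataset construction from transcripts and
    site lists (DRACH filtering, distance-constrained negative sampling,
    redundancy reduction, stratified splitting), classification metrics,
    cross-condition transfer evaluation, and a synthetic planted-motif
    data generator for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
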