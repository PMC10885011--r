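Package: enhancerlm
Title: Two-Layer Enhancer Identification and Strength Prediction from DNA
    Sequence via k-mer Language-Model Transfer Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies enhancer regions in fixed-length DNA sequences and
    predicts their strength (strong versus weak) with a two-stage model: a
    self-supervised k-mer language model (stochastic embedding layer feeding a
    stack of three weight-dropped LSTM layers trained by next-k-mer
    prediction) whose hidden states are classified by a convolutional layer
    with scaled dot-product attention, batch normalization, dropout and a
    softmax output. Includes FASTA and benchmark-layout loaders, a synthetic
    sequence generator with a tunable GC-composition and A/T homopolymer-run
    class signal, stratified cross-validation, grid search, a k-mer-size
    sweep, a language-model ablation driver, and a six-measure evaluation
    suite (accuracy, sensitivity, specificity, Matthews correlation,
    AUROC, AUPRC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
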