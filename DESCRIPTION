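Package: eogdeco
Title: Context-Dependent Hidden Markov Model Recognition of Continuous
    Eye-Motion Sequences from Electrooculography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for recognizing continuous eye-motion sequences from
    multi-channel electrooculography (EOG) signals and mapping them to Kana
    characters for assistive communication.  Implements left-to-right
    Gaussian-mixture hidden Markov models with Baum-Welch training, mono-,
    bi- and tri-eye-motion context-dependent units with decision-tree state
    tying, character n-gram language models with backoff smoothing, a
    Viterbi decoder with language-model weighting and an insertion penalty,
    MLLR and MAP user adaptation, a threshold-plus-voting baseline
    recognizer, edit-distance error-rate scoring, and a synthetic EOG
    generator for desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
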