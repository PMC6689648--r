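Package: songgrammar
Title: Grammar Induction for Animal Song with HDP-PCFG and HDP-HMM Models
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for probabilistic grammatical analysis of
    animal song. Converts audio recordings into strings of mel-frequency
    cepstral coefficient (MFCC) vectors via band-energy song-region detection,
    Hilbert-envelope syllable peak finding and per-peak MFCC extraction; fits
    a hierarchical Dirichlet process probabilistic context-free grammar
    (HDP-PCFG) with variable root and Gaussian terminal emissions, and an
    HDP hidden Markov model baseline, by truncated mean-field coordinate
    ascent variational inference; and reports posterior diagnostics: expected
    counts of left-branching, right-branching and non-regular parses,
    posterior predictive densities, and expected rule-type counts measuring
    grammar compactness. Includes a synthetic-data generator with known
    ground-truth grammars and pulse-train audio for fully reproducible tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
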