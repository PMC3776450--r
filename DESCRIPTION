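Package: softcall
Title: Model-Based Base Calling for Sequencing-by-Synthesis Intensity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical base calling for Illumina-style sequencing-by-synthesis
    platforms from per-cycle four-channel fluorescence intensities. Implements a
    parametric intensity model with crosstalk, phasing/pre-phasing, signal droop,
    inter-cycle leakage and multiplicative Gaussian noise; exact posterior
    decoding on a 16-state base-pair trellis by the forward-backward algorithm
    and approximate posteriors by a soft-output Viterbi algorithm; windowed
    online expectation-maximization for unsupervised (or reference-supervised)
    parameter estimation; a Bustard-style matrix-inversion baseline caller;
    a generative tile simulator for end-to-end validation; and evaluation
    utilities (Hamming-distance alignment, per-cycle error rates, quality-score
    discrimination ability).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
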