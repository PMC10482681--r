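Package: coldstate
Title: Behavioural State Segmentation and Metabolic Coupling Analysis for
    Cold-Exposure Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for cold-induced energy compensation studies
    in mice. Segments one-second behavioural ethograms into latent states
    with a categorical hidden Markov model (multi-sequence Baum-Welch
    fitting, Viterbi decoding, semantic state labelling), summarises state
    occupancy, bouts and transitions, quantifies two-channel fibre
    photometry (reference-corrected dF/F, peri-event AUC and peak),
    computes energy expenditure from indirect calorimetry via the Weir
    equation and detects the onset of energy-expenditure/food-intake
    coupling, and scores real-time place preference and open-field
    trajectories. Includes seeded synthetic-data generators for every
    input so each stage can be validated against known ground truth.
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
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
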