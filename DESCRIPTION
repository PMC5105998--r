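Package: nrfkit
Title: Network Receptive Field Models for Sensory Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Fits and interprets network receptive field (NRF) encoding models
    of sensory neurons: cochleagram preprocessing of natural-sound stimuli,
    peri-stimulus time histogram (PSTH) construction and noise-ratio screening,
    L1-regularized linear-nonlinear (LN) baselines and feedforward-network
    models trained by proximal gradient descent, a train/validation/test
    protocol with lambda cross-validation, noise-corrected prediction metrics
    (CC_norm via split-half reliability), and post-fit analyses of network
    structure (effective hidden units, excitatory/inhibitory and
    expansive/compressive scores, tuning widths, gain control, and conjunctive
    feature selectivity). Includes a synthetic-data generator with known
    ground-truth networks for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    grDevices,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
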