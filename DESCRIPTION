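Package: licklock
Title: Purkinje-Cell Spike-Train Analysis of Rhythmic Licking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing cerebellar Purkinje-cell simple- and
    complex-spike activity recorded during rhythmic licking in head-fixed
    mice. Provides bout segmentation of lick trains, peri-stimulus time
    histograms with baseline Z-scoring, phase-transform coherence between
    spiking and the lick cycle, autocorrelogram power inside and outside
    licking bouts, tongue-endpoint ("rosette") kinematic maps, a
    gradient-boosted-tree decoder of lick versus no-lick epochs with
    Shapley-style feature attribution, and analyses of lick-port
    perturbation and optogenetic stimulation trials. A seeded generative
    model of complete sessions with known ground-truth coupling
    parameters makes every analysis stage testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
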