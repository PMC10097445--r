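Package: chestmotion
Title: Seated Chest-Movement Recognition and Navon Switch-Cost Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for recognising subtle seated chest movements from
    smartphone triaxial accelerometer streams and for analysing their
    relation to attentional switching performance and stress. Provides a
    labelled-signal simulator for six instructed movements (walking,
    standing up and sitting down, rotating, swinging, rocking, sitting
    still), sliding-window preprocessing with per-window gravity correction
    and magnitude spectra, a compact two-layer LSTM sequence classifier
    trained by stochastic gradient descent with momentum and evaluated by
    leave-one-subject-out cross-validation, window-count summaries of long
    unlabeled recordings, and the companion statistical toolkit: shift and
    nonshift trial tagging for the mixed Navon phase, Greenhouse-Geisser
    corrected repeated-measures ANOVA, pooled-error pairwise comparisons,
    pairwise-deletion correlation matrices, and a bias-corrected percentile
    bootstrap mediation model linking movement counts to accuracy and
    salivary alpha-amylase stress through shift-trial reaction time, with a
    subject-table simulator for planted-effect validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    car,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
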