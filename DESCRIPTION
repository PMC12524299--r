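Package: tdsliking
Title: Predicting Temporal Liking Curves from Temporal Dominance of
    Sensations Data with Echo State Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for temporal sensory analysis of foods and food
    pairings. Builds time-normalized temporal dominance of sensations
    (TDS) dominance-proportion curves and temporal liking (TL) curves
    from raw panel event logs, augments small panels by bootstrap
    resampling of panelist curve pairs, and predicts TL curves from TDS
    curves with an echo state network (fixed random reservoir, ridge
    regression readout) optionally fed constant auxiliary flag inputs
    describing the sample context. Includes a synthetic sensory-panel
    generator for end-to-end validation, a leave-one-pairing-out
    evaluation pipeline with median/IQR RMSE reporting, and architecture
    ranking across reservoir sizes and flag encodings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
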