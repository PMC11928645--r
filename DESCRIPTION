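Package: pevdecode
Title: Percent-Explained-Variance and Population-Decoding Analyses for
    Cued Change-Detection Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for trial-structured extracellular
    recordings from a delayed change-detection task with spatial
    pre-cues. Provides sliding-window firing-rate binning, ANOVA effect
    sizes (omega-squared and partial omega-squared) as percent explained
    variance with permutation-null bands, attentional-shift (delta PEV)
    statistics, cross-temporal pseudo-population decoding with shuffled
    baselines and cluster significance, cross-trial-type transfer
    classification, behavioral block-preference analysis, and a synthetic
    session generator emulating the task for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    knitr
Config/testthat/edition: 3
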