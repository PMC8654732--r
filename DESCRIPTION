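Package: srsclust
Title: Seizure Cluster Analysis for Chronic EEG Monitoring in Kindled Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and characterization of spontaneous recurrent seizure
    (SRS) clusters from chronic single-channel EEG monitoring in the mouse
    extended hippocampal kindling model. Provides an envelope-threshold ictal
    discharge detector (amplitude at least 2-fold a robust background estimate,
    duration at least 10 s), inter-seizure-interval (ISI) statistics and
    histograms, severity-versus-ISI analyses (Pearson correlation of discharge
    duration with ISI, Kruskal-Wallis comparison of Racine scores across ISI
    strata), run-based seizure-cluster segmentation (at least 4 consecutive
    seizures with successive ISIs at most 120 min), cluster grouping, circadian
    light-on/light-off expression summaries with paired testing, and Spearman
    trend tests within tight clusters. A Neyman-Scott-style clustered,
    circadian-modulated point-process simulator with synthetic EEG rendering
    makes every stage testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'phase.R'
    'io.R'
    'simulate-events.R'
    'simulate-eeg.R'
    'detect.R'
    'isi.R'
    'clusters.R'
    'pipeline.R'
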