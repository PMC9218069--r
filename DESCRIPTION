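Package: chronicsense
Title: Chronic DBS Sensing Analyses for Implanted Stimulation-Recording Systems
Version: 0.1.0
Authors@R: person("Chronic", "Sense", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for chronic neural sensing from fully implanted
    deep-brain-stimulation (DBS) systems recording in the limbic (Papez)
    circuit: stimulus-artifact-triggered evoked-potential averaging, Welch/Hann
    local-field-potential spectral quantification, directional-lead contact
    ranking, stimulation-induced suppression and after-discharge
    classification, cross-region event-lag estimation, and electrode impedance
    trending. A seeded synthetic cohort generator reproduces the statistical
    structure these analyses assume (theta-dominant hippocampal LFP,
    sharp-wave propagation to thalamus, far-field K-complexes, directional
    segment gain asymmetry, impedance stabilization and lead breakage) so the
    whole pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
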