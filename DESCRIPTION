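Package: spineburst
Title: Quantification of Epileptiform Bursts, Dendritic Spine Volume and
    Synaptic Plasticity in Hippocampal Slice Experiments
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative readouts of hippocampal plasticity
    experiments: detection and classification of epileptiform burst events in
    CA3 extracellular recordings (band-pass filtering, MAD-based spike
    thresholding, sliding-window hysteresis), time-lapse two-photon dendritic
    spine volume quantification (projection, translation registration, ROI
    integration with background and reference correction, baseline drift QC),
    fEPSP initial-slope and LTD magnitude measurement, 35S metabolic-labeling
    normalization, and the accompanying statistics layer (outlier rule,
    mean +/- SEM, Student's t, one-way ANOVA with Bonferroni post hoc, exact
    two-sided Fisher test). A seeded synthetic-data generator provides
    ground-truth electrophysiology traces, image stack series, fEPSP sessions,
    labeling tables and seizure cohorts so that every stage is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    tiff,
    jsonlite,
    yaml,
    withr,
    data.table
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
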