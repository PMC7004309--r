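Package: tcdflow
Title: Unsupervised Flow-Typing of Transcranial Doppler Beat Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for morphological analysis of transcranial Doppler (TCD)
    cerebral blood flow velocity recordings. Raw pulsatile recordings are
    segmented into beats, cleaned by iterated interquartile-range outlier
    rejection, ensemble-averaged, smoothed, and normalized in velocity and
    time. Three morphological features (onset of maximal velocity, systolic
    canopy length, and a weighted peak/trough count) are extracted from each
    normalized beat, and the resulting feature space is partitioned by
    spectral clustering with the cluster number selected by the gap
    statistic. Cluster exemplars, five-member archetypes and subject-group
    composition summaries describe the discovered flow types. A synthetic
    waveform generator with known ground truth supports validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    signal,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    kernlab
Config/testthat/edition: 3
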