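Package: pamscape
Title: Passive Acoustic Monitoring to Landscape Occurrence Pipelines
Version: 0.1.0
Authors@R: person("Osa", "Bioacoustics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale, fully synthetic re-implementation of a
    semi-automated passive acoustic monitoring (PAM) workflow for a rare
    vocal primate: synthetic rainforest soundscapes with frequency-modulated
    contact calls, a convolutional detector with squeeze-and-excitation
    recalibration and multi-head attention pooling, simulated verification of
    detections into 7-day detection histories, and the downstream landscape
    statistics (buffer covariates, scale-of-effect screening, Firth
    bias-reduced logistic regression under complete separation, Moran's I and
    autocovariate spatial diagnostics, hierarchical variance partitioning and
    a constant-psi constant-p null occupancy model).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
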