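Package: tonotopy
Title: Quantification of Spontaneous and Sound-Evoked Activity in the
    Developing Auditory System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Event-based quantification of calcium imaging and audiometric
    recordings from the developing auditory system. Implements delta-F-over-F
    normalization, grid-ROI binarization and 3D spatiotemporal event
    segmentation for inner supporting cell activity, hair-cell and spiral
    ganglion neuron synchrony and coupling statistics, transmitted-light
    crenation detection, widefield inferior-colliculus tonotopic line-scan
    statistics, automated ABR and DPOAE threshold estimation, and two-photon
    tuning-curve analysis (best frequency, Gaussian bandwidth, PCA response
    features). Ships seeded synthetic-data generators that emulate each
    recording modality with planted ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    igraph,
    jsonlite,
    minpack.lm,
    pracma,
    rlang,
    tiff
Suggests:
    cluster,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
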