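Package: berryhsi
Title: Hyperspectral Imaging Chemometrics for Strawberry Quality
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end pipeline for predicting strawberry quality
    parameters (soluble solid content, pH, vitamin C) from visible/near-
    infrared hyperspectral reflectance images. Covers white/dark reference
    calibration, super-red fruit segmentation, mean-spectrum extraction,
    wavelet denoising and multiplicative scatter correction, color-moment
    and gray level-gradient co-occurrence matrix / Gabor texture features,
    CARS and UVE variable selection, grouped Kennard-Stone sample
    partitioning, PLSR / SVR / locally weighted regression models, and
    pixel-wise quality distribution maps. Includes a synthetic-scene
    generator that emulates the statistical structure of a fruit storage
    experiment so the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    e1071,
    png,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
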