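Package: phenocrop
Title: Phenology-Based Cropping-Pattern Mapping from Satellite
    Reflectance Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Maps annual cropping patterns (cropping intensity plus the
    sequence of rice, wheat and maize seasons) from per-pixel multispectral
    surface-reflectance time series at an 8-day cadence. Computes the EVI2,
    LSWI and NMDI spectral indices, reconstructs daily trajectories with a
    Whittaker smoother, detects cropping intensity from Mexican-hat wavelet
    spectra of the EVI2 series, classifies each growing season with
    pixel-purity-stratified phenological decision rules, encodes the result
    as integer cropping-pattern codes, and assesses map accuracy (overall
    accuracy, user's and producer's accuracy, F1, kappa) and region-level
    sown-area agreement. A seeded scene simulator generates reflectance
    stacks with known ground truth so the whole pipeline can be exercised
    end to end without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
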