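Package: hsichemo
Title: Hyperspectral Chemometrics for Fruit Quality Prediction and Origin
    Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tidyverse-native chemometrics toolkit for visible/near-infrared
    hyperspectral imaging of fruit. Reads and calibrates ENVI-format
    hypercubes, extracts region-of-interest mean spectra, applies the standard
    spectral pretreatments (multiplicative scatter correction, standard normal
    variate, Savitzky-Golay smoothing and derivatives, mean centering),
    partitions samples with the SPXY (sample set partitioning based on joint
    x-y distances) algorithm, fits NIPALS partial least squares regression and
    PLS-DA / random-forest classifiers with cross-validated model selection,
    and screens informative wavelengths with competitive adaptive reweighted
    sampling (CARS) and the random frog algorithm. A seeded synthetic-spectra
    generator with known informative bands supports end-to-end validation of
    the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
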