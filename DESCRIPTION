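Package: lacto2dspec
Title: Milk Freshness Discrimination from Synchronous 2D Vis/NIR
    Correlation Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric pipeline for discriminating raw-milk freshness from
    visible/near-infrared (400-2500 nm) absorbance spectra. Computes
    generalized two-dimensional correlation spectra against a fresh-milk
    reference, extracts autocorrelation and cross-peak features, and fits
    three classifier families: a peak-threshold rule, trace-ratio linear
    discriminant analysis, and kernel support vector machines tuned by grid
    search and particle swarm optimization. Includes spectral pretreatments
    (standard normal variate, multiplicative scatter correction,
    Savitzky-Golay first derivative), accuracy-based evaluation with
    titratable-acidity class mapping, and a synthetic generator of milk-like
    storage series for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
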