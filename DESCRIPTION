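Package: paddywave
Title: Multi-Stage Canopy Spectra Transforms and Rice Yield Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating rice grain yield from canopy reflectance
    spectra measured at several growth stages. Implements the spectral
    transforms used in hyperspectral crop phenotyping (Savitzky-Golay
    smoothing, first derivative, continuum removal by upper convex hull,
    and the continuous wavelet transform at dyadic scales), extraction of
    vegetation indices and red/blue/yellow edge parameters, correlation
    screening of yield-sensitive bands and wavelet coefficients,
    multi-growth-stage feature fusion, and yield regression by stepwise
    multiple linear regression or random forest, evaluated with R-squared,
    RMSE and MAPE. A calibrated synthetic canopy-spectra generator with a
    known latent link between stage-wise spectra and yield makes the whole
    pipeline reproducible without field data.
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
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
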