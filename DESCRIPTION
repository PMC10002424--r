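Package: soilcalib
Title: Ensemble and MCMC Calibration of a Soil-Crop Water Balance Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Kalman-formula-based parameter estimation for soil-crop system
    models: the ensemble smoother with multiple data assimilation (ES-MDA),
    the iterative local updating ensemble smoother (ILUES), and the DREAM(ZS)
    family of adaptive multi-chain MCMC samplers, including a variant with a
    Kalman-inspired proposal used during burn-in (DREAMkzs). Ships a fast
    tipping-bucket soil water balance surrogate with FAO-56-style crop
    evapotranspiration so the samplers can be exercised end-to-end on a
    45-parameter soil hydraulic / nitrogen / crop parameter space, together
    with synthetic-data generators, fit statistics (ME, RMSE, index of
    agreement), uncertainty bands and tidy/ggplot2 result methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
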