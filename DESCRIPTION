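Package: durerp
Title: Duration Effects and Overlap Correction for Regression ERPs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and estimation toolkit for event-related brain
    responses whose shape depends on event duration and which overlap in
    time. Provides parametric duration-modulated ground-truth kernels, a
    continuous-signal simulator with collinear duration/overlap structure,
    mass-univariate and FIR-deconvolution regression with linear,
    categorical and B-spline duration encodings, marginal-effect summaries,
    a normalized-MSE evaluation sweep, and group-level inference
    (Hotelling T-squared on spline coefficients with Benjamini-Yekutieli
    false discovery rate control).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    splines,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
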