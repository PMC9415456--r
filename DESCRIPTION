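Package: dsmflow
Title: Uncertainty Propagation for Density Surface Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fitting density surface models (DSMs) to line-transect
    distance sampling survey data and, centrally, for propagating uncertainty
    from every model component into final abundance estimates. Fits
    covariate-dependent half-normal detection functions by maximum likelihood,
    fits penalized regression spline GAMs to segment counts with detectability
    offsets, absorbs detection-function parameter uncertainty into the spatial
    model by refitting with a fixed-covariance random effect, simulates
    coefficient vectors from the approximate posterior, streams per-cell and
    per-period abundance summaries over time-indexed prediction grids using
    online (Welford) variance updates, combines non-coincident correction
    factors (trackline detection g(0), availability) by the delta method, and
    reports abundance time series with log-normal intervals. A synthetic
    line-transect survey simulator with known truth supports validation and
    coverage studies.
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
    mgcv,
    purrr,
    readr,
    rlang,
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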