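Package: tvdlnm
Title: Time-Varying Distributed Lag Non-Linear Models for
    Temperature-Mortality Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits quasi-Poisson time-series regressions with a
    bi-dimensional temperature crossbasis (natural cubic splines in the
    exposure and lag dimensions) and a linear interaction between
    calendar time and the crossbasis, so that the exposure-lag-response
    surface may drift over the study period.  Provides annual adaptation
    indicators derived from the fitted surface: percentile-constricted
    minimum mortality temperatures with parametric-bootstrap empirical
    confidence intervals, lag-cumulated relative risks at extreme and
    moderate temperature percentiles, multivariate Wald tests of
    temporal change, and inverse-variance weighted trend regressions.
    Includes a synthetic daily mortality-weather generator with known
    ground truth for validation, and an end-to-end pipeline with a
    qAIC-based sensitivity harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    graphics,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
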