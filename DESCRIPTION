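Package: fdamort
Title: Functional Regression Models for Weather-Related Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Functional data analysis tools for temperature-mortality
    epidemiology. Builds functional data from discrete temperature and
    mortality measurements by B-spline smoothing with cross-validated knot
    selection, fits a scalar-response functional linear model (daily death
    counts on the previous day's 24-hour temperature curve) with wild
    bootstrap confidence bands, fits a historical fully functional linear
    model (annual log-mortality curves on same-year temperature with a
    60-day lag constraint), implements classical lag-GAM and distributed
    lag non-linear model (DLNM) baselines, and compares all models by
    blocked leave-one-year-out cross-validated RMSE. A seeded synthetic
    weather-mortality generator makes the whole pipeline testable without
    access to administrative health data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    splines,
    utils,
    pracma,
    mgcv,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
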