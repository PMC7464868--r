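Package: dustlag
Title: Distributed-Lag Dust Exposure and Exacerbation Risk Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for reconstructing particulate-matter exposure from
    satellite aerosol optical depth (AOD) and studying its association with
    acute exacerbations of chronic obstructive pulmonary disease (AECOPD).
    Includes collocation of AOD retrievals with ground PM2.5 monitors and an
    empirical calibration regression with heteroskedasticity-robust intervals,
    principal-component summaries of meteorological covariates, local
    space-time ordinary kriging of daily PM2.5 and temperature to residences,
    dust-day detection and intensity grading from LIDAR volume depolarization
    ratios, inverse-time-weighted distributed-lag exposure construction,
    cluster-robust logistic risk models with a 0-15 day lag sweep, stratified
    environmental summaries, and a synthetic cohort generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    jsonlite
Config/testthat/edition: 3
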