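Package: pretermsae
Title: Small-Area Estimation of County Preterm Birth Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian small-area estimation of annual county-level preterm and
    early preterm birth rates from tabulated vital-statistics counts. Fits a
    Besag-York-Mollie (BYM) space-time-age conditional autoregressive model by
    Markov chain Monte Carlo, directly age-standardizes the smoothed rates,
    summarizes geographic disparities with percentile-gap statistics, relates
    county rates to the Social Vulnerability Index with negative binomial and
    least-squares regression, and classifies per-county log-linear trends.
    Includes a synthetic vital-statistics generator with spatially correlated
    true rates so the full pipeline is testable without restricted natality
    microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    Matrix,
    igraph,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
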