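Package: fluxsample
Title: Monte Carlo Subsampling Design for Plot-Scale Soil CO2 Emission Estimates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how spatial variability and sample size drive
    uncertainty in plot-scale soil CO2 emission estimates. Implements repeated
    random subsampling without replacement to estimate the coefficient of
    variation of the subsample mean at every sample size, together with two
    independent oracles (exhaustive enumeration and the finite-population
    closed form); fits the three classic empirical soil-respiration models
    (exponential in temperature, power in moisture, and their interaction) by
    nonlinear least squares; integrates per-collar CO2 efflux over the growing
    season from continuous half-hourly driver records; detects the optimal
    sample size from a CV curve by the dCV/dn > -1 threshold rule; propagates
    driver estimation errors into relative flux errors by first-order total
    derivatives; and ships a seeded synthetic field-campaign generator
    emulating an irrigated oasis maize plot so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    pracma,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
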