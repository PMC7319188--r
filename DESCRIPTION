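Package: simexpo
Title: Simulation of Exposure Measurement Error in Multilevel Air Pollution
    Epidemiology
Version: 0.1.0
Authors@R:
    person("STEAM", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Monte Carlo framework for assessing how measurement error in
    modeled air-pollution exposures biases health-effect estimates, coverage
    and power in a multilevel Poisson analysis that jointly estimates
    short-term (daily) and long-term (period-mean) effects. Simulates "true"
    daily pollutant concentrations over a network of small areas from a
    spatio-temporal model (spatially correlated area means, seasonality,
    autocorrelated common daily shocks), simulates Poisson outcome counts
    under prespecified concentration-response functions, injects error into
    the exposure with prespecified temporal/spatial correlation coefficients
    and variance ratios (additive or proportional scale), and refits the
    multilevel model. Also estimates those error parameters from paired
    model-monitor validation data with instrument-error correction, and
    computes standard air-quality model validation metrics (MB, NMB, NMGE,
    RMSE, FAC2) with leave-out splitting utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
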