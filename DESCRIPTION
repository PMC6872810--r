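Package: joinpointSPM
Title: Joinpoint Regression and Bayesian Surplus Production Models for
    Regime Shifts in Harvested Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting and accounting for sudden changes in the
    dynamics of a harvested population. Simulates Schaefer
    surplus-production (biomass dynamics) time series containing a
    structural change in growth rate and catchability, estimates the
    change year from catch-per-unit-effort by multi-start two-breakpoint
    segmented regression, fits a Bayesian state-space surplus-production
    model by MCMC (via JAGS) with the change point ignored, estimated, or
    known, and orchestrates simulation studies that quantify change-point
    accuracy, transition-period length, and the relative bias of
    growth-rate and catchability estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rjags,
    coda,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
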