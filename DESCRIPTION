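Package: lifedecomp
Title: Cause-Decomposed Period Life Tables for Attributable Mortality Burden
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds multiple-decrement period life tables from aggregate
    death counts and person-years by single year of age, smooths
    cause-specific mortality rates with Poisson regression on a natural
    cubic spline of age, attributes fractions of each cause of death to
    exposures (tobacco smoking, illegal drugs), evaluates counterfactual
    elimination scenarios under competing risks, and propagates
    uncertainty by Poisson Monte-Carlo resampling of the death counts.
    Includes a synthetic-data generator that emulates the hazard
    structure of a cohort of people who use illegal opioids, so the
    whole pipeline is testable without access to individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
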