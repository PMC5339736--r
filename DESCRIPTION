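Package: irristoch
Title: Stochastic Population Dynamics of Irrigated Social-Ecological Systems
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A stylized stochastic model of an irrigated social-ecological
    system: a discrete-time birth-death process for the irrigator population
    whose entry and exit rates respond to the per-capita payoff of farming
    inside the system relative to outside opportunities. Payoffs couple water
    availability, taxation, and tax-funded maintenance of shared irrigation
    infrastructure, producing a maintenance threshold, a bistable population
    landscape, and a one-way collapse trap under strong environmental or
    institutional stochasticity. Provides calibrated threshold calculators,
    moment-matched lognormal and beta annual drivers, a compiled simulator
    with two transition schemes, exact product-form stationary distributions
    as analytic oracles, collapse-detection experiments, and a command-line
    interface with experiment presets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
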