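Package: groupsoc
Title: Cooperation, Power, and Inequality Dynamics in Group-Structured Societies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Agent-based simulation and analytics for a society subdivided
    into groups of bounded-rational individuals. Individuals play a
    nonlinear public goods game within their group; groups invest their
    production into a between-group club goods game and compete for
    political power through a Tullock contest whose outcome sets how the
    jointly produced resource is divided. Strategies are revised by myopic
    best response with logit (quantal-response) errors. The package
    provides the time-stepping engine, ensemble runners and parameter
    sweeps, summary statistics (coalition size, Gini index of power among
    cooperating groups, effort dispersion, regime and elite-structure
    classification), and closed-form equilibrium approximations with
    existence and stability conditions, including a numerical
    power-stability probe.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
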