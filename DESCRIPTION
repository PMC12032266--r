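Package: tripgame
Title: Tripartite Evolutionary Game Analysis of Smart Senior-Care Platform Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the regulation of smart health senior-care service platforms as a
    three-population evolutionary game between a government (positive versus passive
    regulation), a platform operator (opportunism versus reciprocity) and senior-care
    service enterprises (positive versus passive cooperation). Provides the payoff
    model over all eight pure-strategy profiles, the coupled replicator dynamics on
    the unit cube with adaptive integration, closed-form Jacobian and corner-equilibrium
    eigenvalues with evolutionarily-stable-strategy classification under the stability
    conditions I-V, five built-in validation scenarios plus a constrained random
    scenario sampler, and parameter sweeps with analytic and bisection estimates of
    critical policy thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
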