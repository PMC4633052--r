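Package: quadpop
Title: Design-Unbiased Population Size Estimation from Random Quadrat Grids
Version: 0.1.0
Authors@R:
    person("quadpop", "developers", email = "quadpop@example.org", role = c("aut", "cre"))
Description: Estimates the number of particles (people, animals, trees) lying
    on an essentially planar region from counts in a uniformly-random
    systematic grid of square quadrats. Provides the design-unbiased number
    estimator, a naive independence-based error variance estimator and a
    Cavalieri-stripes variance estimator with a splitting within-stripe term,
    edge-effect-unbiased counting rules (associated point and forbidden line),
    a systematic Monte Carlo resampling validator, synthetic point-pattern
    generators, a grid-design planner, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
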