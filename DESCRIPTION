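Package: dendroseq
Title: Sequence Discrimination by Dendritic Reaction-Diffusion Chemistry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic one-dimensional reaction-diffusion simulation of
    dendritic sequence discrimination. Provides an operator-split integrator
    (adaptive Runge-Kutta-Fehlberg reactions, implicit backward-Euler
    diffusion on chains and spiny trees), four abstract two-species
    chemistries (negative feedback, feedforward inhibition,
    FitzHugh-Nagumo, and a bistable switch with delayed inhibition), a
    schematic mass-action MAPK switch on a spiny cylinder, the sequence-order
    metric Q, the selectivity statistic, and the space-by-time tuning,
    rate-scaling, amplitude and parameter-sensitivity sweep protocols
    built on them.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    yaml,
    xml2,
    arrow
Config/testthat/edition: 3
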