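Package: bistablefronts
Title: Bistable Gene-Expression Boundary Dynamics over Time-Varying Morphogen Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of gene-expression boundary formation by
    bistable genetic networks (toggle switches, Hunchback-Bicoid, a scalar
    cubic model) reading static or time-varying morphogen gradients.
    Implements instantaneous phase-portrait and bifurcation scans along the
    tissue axis, an irregularity/precision metric R based on tight
    basin-of-attraction bounds over initial-condition ensembles, a
    method-of-lines reaction-diffusion solver with no-flux boundaries, local
    (frozen-parameter) travelling-front velocity maps, a single-variable ODE
    approximation of propagating boundary position, and front-localization
    analysis for antiparallel morphogen gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
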