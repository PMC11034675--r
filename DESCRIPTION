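Package: glvcomm
Title: Generalized Lotka-Volterra Modelling of Phage-Perturbed Bacterial
    Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation, hierarchical fitting and ecological analysis of
    generalized Lotka-Volterra (gLV) models for small bacterial communities
    grown under serial-transfer culture. Growth rates are fixed from
    monoculture time series, interaction coefficients are estimated from
    2- and 3-species coculture data by bounded multi-start nonlinear least
    squares, and assembled interaction matrices are used to predict
    full-community dynamics, classify long-run survivor sets, compute
    invasion growth rates, and formalise phage-mediated competitive
    release. Includes community summary metrics (qPCR copy-number
    adjustment, Shannon diversity, Malthusian selection rate, fold change)
    and a synthetic factorial coculture generator with known ground truth,
    including an explicit phage-host model with resistance evolution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
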