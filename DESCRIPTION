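Package: betaGSIS
Title: Kinetic and Flux-Regression Modeling of Beta-Cell Glucose-Stimulated
    Insulin Secretion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A compartmental kinetic model of pancreatic beta-cell central
    carbon metabolism (glycolysis, pentose phosphate pathway, TCA cycle,
    polyol pathway and electron transport chain across cytosol and
    mitochondria) together with the machinery to make it cell-line specific
    and to link it to insulin secretion: stoichiometric conserved-moiety
    analysis, a stiff Rosenbrock ODE integrator, Latin hypercube initial
    conditions, an identifiability screen with equilibrium
    reparameterization, eFAST variance-based global sensitivity analysis,
    particle-swarm fitting of Vmax parameters against fold-change
    metabolomics data, SIMPLS partial least squares regression of reaction
    fluxes onto insulin secretion with VIP scores, and systematic Vmax
    perturbation scans including named pharmacological scenarios. A
    synthetic-data generator with known ground truth stands in for the
    published metabolomics training data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    xml2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
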