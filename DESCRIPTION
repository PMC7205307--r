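Package: xapswitch
Title: Deterministic and Stochastic Analysis of the xapABR Metabolic
    Genetic Switch
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulator and analysis toolkit for a transporter-mediated
    genetic switch of the xapABR type, in which a membrane transporter
    (XapB) imports the inducer of its own operon and a coupled enzyme
    (XapA) degrades it. The regulatory input is modelled mechanistically
    with a Monod-Wyman-Changeux description of transcription-factor
    induction and a thermodynamic (statistical-weight) model of promoter
    occupancy. The package provides the dimensional and nondimensional
    rate equations, fixed-point finding with stability classification,
    the mRNA quasi-steady-state reduction, trajectory integration,
    bifurcation diagrams and bistable-range scans, structural circuit
    variants (transporter/enzyme removal, reduced binding-site counts,
    alternative promoter-activity policies), and discrete-molecule
    stochastic simulation via Gillespie's direct method and a hybrid
    tau-leaping accelerator, including ensemble statistics, bimodality
    splitting, adaptation (first-passage) times and a stochastic
    hysteresis protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
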