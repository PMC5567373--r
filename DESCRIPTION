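Package: metaconc
Title: Predicting Intracellular Metabolite Concentrations from Molecular,
    Network-Topology and Pathway Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: QSAR-style modelling of the negative base-10 logarithm of
    intracellular metabolite concentration (-logC, mol/L) in micro-organisms.
    Reconstructs organism-specific metabolic networks from reactant pairs,
    derives per-node degree and clustering-coefficient descriptors, encodes
    pathway membership as binary variables and collapses the retained ones
    into a single Metabolite Pathways' Feature (MPF) descriptor, selects
    variables by a genetic algorithm with leave-one-out RMSE fitness followed
    by steepest-descent add/remove optimisation, fits epsilon support-vector
    regression with a Gaussian radial-basis kernel, validates by 10-fold,
    leave-one-out and external test-set statistics, and delimits a
    leverage-based applicability domain (Williams plot). A synthetic-data
    generator with a known sparse generative signal makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    kernlab,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
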