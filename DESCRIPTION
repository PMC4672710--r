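Package: mitonet
Title: Quantitative Models of Mitochondrial Network Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale simulation and analysis toolkit for quantitative
    hypotheses about why mitochondria form fused networks. Implements a
    fluctuating bond-percolation lattice of mitochondrial units with
    morphology classification, tracer diffusion on the fluctuating lattice
    together with a dynamic effective-medium prediction of the apparent
    diffusion coefficient, an ordinary differential equation model of
    quality control by selective fusion ("blind surveillance"), a sigmoidal
    bioenergetic model of the ATP-synthesis change on fusion, a
    calcium-dilution model of optimal chain length, and two robustness
    models (a capacitor-leak fluctuation model and a spin-coupled agent
    model of collective failure). Includes scenario configuration, fixture
    generation, and CSV/JSON/GraphML reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    igraph,
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
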