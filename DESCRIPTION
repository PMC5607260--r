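Package: ligandtree
Title: Mechanistic Receptor Signaling Features and Bagged Decision Trees
    for Ligand-Dependent Proliferation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and simulates a mechanistic ordinary-differential-equation
    model of ErbB, IGF-1R and Met receptor signaling (ligand binding, receptor
    homo- and heterodimerization, trafficking, and the MAPK and PI3K cascades
    converging on S6), in which the only cell-line-specific inputs are
    receptor surface expression levels.  Basal states are obtained from
    analytic steady-state constraints, shared kinetics are calibrated by
    multi-start maximum likelihood, and simulated signaling features (areas
    under the curve of phosphorylated dimers and downstream kinases) feed
    bagged decision trees with a signal-to-noise split gain that predict
    ligand-induced proliferation of cell lines and, via mRNA-based receptor
    estimates, of tumor cohorts.  Includes responder calling from viability
    screens (exact Wilcoxon rank-sum), a cell-line split evaluation harness,
    and synthetic-data generators with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    minpack.lm,
    pracma,
    xml2,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rpart,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
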