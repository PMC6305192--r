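Package: resinflux
Title: Cell-Type-Resolved Constraint-Based Flux Analysis of Conifer Needle Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based metabolic modeling of secretory (resin-duct
    epithelial) and photosynthetic (mesophyll) cell types in conifer needles.
    Builds expression-pruned, compartmentalized genome-scale models from a
    reference reaction set and transcript evidence, constructs biomass
    objectives from measured oleoresin and end-product compositions and
    needle/duct geometry, estimates cross-contamination of laser-capture
    microdissected transcriptomes from marker genes, and predicts flux
    distributions by flux balance analysis and expression-weighted flux
    minimization (E-Fmin) under varying photosynthetic activity. Includes a
    miniature plant-cell network and transcriptome simulator so the whole
    pipeline runs without external data. Linear programs are solved with a
    built-in bounded-variable two-phase simplex.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    xml2,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    boot,
    withr,
    Biostrings,
    optparse
Config/testthat/edition: 3
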