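Package: hpfold
Title: Memetic Evolutionary Search for HP-Lattice Protein Structure
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Ab initio coarse-grained protein structure prediction on the
    hydrophobic-polar (HP) lattice model. Implements a two-tier memetic
    framework: a constraint-aware population initializer that emits only
    self-avoiding-walk conformations, and an evolutionary-programming search
    hybridized with a hill-climbing controller, using secondary-structure
    motif mutations (helix, sheet) together with corner and pull moves on 2D
    square and triangular lattices. Includes run-length HP sequence notation
    parsers, amino-acid to HP translation, an exhaustive enumeration oracle
    for short chains, packaged benchmark sequences with reference ground-state
    energies, and experiment drivers that reproduce the benchmark reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
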