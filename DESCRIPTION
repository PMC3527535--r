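Package: knotfold
Title: Lattice Go-Model Folding Simulations of Knotted Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo folding simulations of cubic-lattice Go-model proteins,
    in the bulk and tethered to a chemically inert plane, with an emphasis on
    trefoil-knotted folds. Provides the lattice chain representation and local
    move set (corner flips, end moves, crankshafts), Metropolis and
    replica-exchange sampling, heat-capacity and WHAM free-energy analysis,
    first-passage-time folding kinetics, knot detection via chain closure, KMT
    reduction and the Alexander determinant, knotted-core localization,
    knotting-probability curves, and hierarchical clustering of conformational
    ensembles on contact-map similarity. Includes a constrained stochastic
    designer that builds knotted and unknotted native lattice structures to a
    printed topological specification.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
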