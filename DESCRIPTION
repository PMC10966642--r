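Package: plabackmap
Title: Physics-Informed Neural Backmapping of Coarse-Grained Poly(lactic acid)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reinserts all-atom detail into coarse-grained (one bead per
    monomer) configurations of poly(lactic acid) stereoisomers (PLLA, PDLA
    and their copolymers). Provides the chain topology model with chiral
    alpha carbons, the center-of-mass coarse-graining operator, a
    bond-vector codec between Cartesian coordinates and a padded tensor
    representation, a one-dimensional U-net trained with a composite
    geometric loss (bond vectors, bond lengths, bending angles, dihedral
    angles, anchor vectors), stereochemistry checking and reflection-based
    correction, a synthetic melt-ensemble generator with known geometric
    statistics, and a structural-analysis suite (dihedral distributions,
    radial distribution functions, internal distances, radius of gyration,
    density, block averaging).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
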