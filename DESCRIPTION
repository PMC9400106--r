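Package: taamkit
Title: Atom-Type Analysis for Transferable Aspherical Pseudoatom Data Banks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing multipolar pseudoatom atom-type data banks
    built on the Hansen-Coppens formalism. Represents atom types as chemical
    topology plus multipole parameter sets (kappa, Pval, kappa', Plm),
    evaluates pseudoatom electron densities, enumerates and realizes local
    coordinate systems from neighbor geometry, rotates multipole populations
    between frames, derives site-symmetry-allowed multipole index sets from
    point-group generators, classifies atom types by chemical topology into
    hierarchical trees, and clusters them by electron-density parameters with
    multi-level DBSCAN using knee-method epsilon estimation. A seeded
    synthetic-bank generator with planted clusters provides a fully
    controlled test substrate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), mclust, igraph, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
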