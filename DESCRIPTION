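Package: swdock
Title: Rigid-Body Monte Carlo Ensemble Docking with Square-Well Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: All-atom rigid-body protein-protein docking driven by a
    piecewise-constant (square-well) cost function combining hydrogen-bond,
    double-well electrostatic and SASA-derived hydropathy potentials.
    Monte Carlo ensemble docking (MC-ED) builds converged ensembles of
    dimers (or dimer-of-dimer tetramers) from pools of conformers, and the
    analysis layer computes binding-energy density modes, intermolecular
    residue-residue contact probability maps and aggregation hot-spot
    rankings. Includes pH-aware protonation assignment from per-residue
    pKa tables, deterministic synthetic-structure generators and
    brute-force oracles for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    bio3d,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
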