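Package: swarmdock
Title: Diversity-Guided Lamarckian Random Drift Particle Swarm Search for
    Flexible Ligand Docking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Swarm-based stochastic search for flexible ligand docking.
    Implements the random drift particle swarm optimizer (RDPSO) with a
    two-phased diversity control strategy (2PDC) and Solis-Wets local
    search (the DGLRDPSO hybrid), alongside Lamarckian PSO and Lamarckian
    RDPSO baselines. Ships a simplified grid-based docking objective
    (torsion-tree ligand kinematics, precomputed receptor affinity and
    electrostatic maps with trilinear interpolation, ligand internal
    energy), a PDBQT-subset reader and writer, a seeded generator of
    synthetic re-docking fixtures with a certified energy funnel, and the
    standard evaluation indexes for docking benchmarks (coordinate RMSD,
    differences to the per-case reference algorithm, success counting at
    2 Angstrom, rank conventions).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
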