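Package: mmforge
Title: Molecular Mechanics Toolkit: Force-Field Optimisation, Dynamics,
    Crystal Lattice Sums and Knowledge-Based Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A scriptable molecular modelling toolkit for structural
    bioinformatics.  Provides an AMBER/GAFF-functional-form force field
    with damped-shifted-force electrostatics and analytic gradients,
    energy minimisation by limited-memory BFGS and Powell-Beale
    restarted conjugate gradients with atom freezing, velocity-Verlet
    molecular dynamics with Berendsen temperature coupling, crystal
    lattice-energy evaluation and optimisation on a supercell expansion
    with neutral charge groups, knowledge-based pair potentials (PMF and
    DFIRE-style Boltzmann inversion) for interactive-docking scores and
    rotamer-space scanning, Z-matrix protein editing (torsions,
    mutation, Ramachandran classification), hydrogen placement and
    polar-hydrogen optimisation, solvent-accessible and polar surface
    areas, three-point molecular alignment, and PDB/XYZ/Z-matrix text
    input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite
Config/testthat/edition: 3
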