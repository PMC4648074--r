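Package: fdpb
Title: Finite-Difference Poisson-Boltzmann Electrostatics with Implicit Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Numerical solution of the linearized Poisson-Boltzmann equation
    for biomolecular solutes on a uniform grid. Builds solvent-excluded
    molecular-surface-aware dielectric and ion-screening maps (including an
    ion-exclusion layer and an implicit membrane slab), solves the
    finite-difference equations by red-black Gauss-Seidel with successive
    over-relaxation under zero, quasi-Coulombic, or per-axis periodic
    boundary conditions, and computes electrostatic solvation free energies
    both by reference-state subtraction and by induced boundary charges.
    Reads PDB/PQR structures with DelPhi-style radius and charge tables and
    writes OpenDX potential maps, potential profiles, and plain-text reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
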