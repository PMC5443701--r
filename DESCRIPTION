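Package: pbcharge
Title: Charge Regulation and Renormalization of Macromolecules via the
    Nonlinear Poisson-Boltzmann Equation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mean-field continuum electrostatics for globular macromolecules
    and linear polyelectrolytes in monovalent electrolyte. Computes the
    structural (Henderson-Hasselbalch) charge, the regulated (true net)
    charge obtained by coupling acid-base ionization equilibria to the local
    electrostatic potential, and the renormalized (effective, interaction)
    charge extracted from electrostatic interaction free energies in a
    charged parallel-plate slit. Includes finite-volume solvers for the
    nonlinear Poisson-Boltzmann equation in 1-D radial (sphere, infinite
    cylinder, core-shell sphere) and 2-D axisymmetric (finite cylinder or
    sphere in a slit) geometries, charge-regulation threshold criteria,
    titration curves and isoelectric points, interior-dielectric inference
    from a measured charge, and core-shell pKa-shift predictions for buried
    ionizable residues.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
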