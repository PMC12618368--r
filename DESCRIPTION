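Package: hemofsi
Title: Two-Phase Pulsatile Blood Flow and Fluid-Structure Interaction in
    Compliant Coronary Arteries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale haemodynamic modelling of coronary arteries with an
    Eulerian-Eulerian two-phase (plasma plus red-blood-cell) description of
    blood. Red blood cells are treated as a granular phase with kinetic-theory
    closures (radial distribution function, solids pressure, granular bulk and
    shear viscosity, Gidaspow drag), coupled to plasma on a radially resolved
    axisymmetric grid per centerline station. The lumen is two-way coupled to
    a two-layer viscohyperelastic vessel wall (five-parameter Mooney-Rivlin
    plus five-term Prony shear relaxation) through a partitioned, under-relaxed
    fixed-point loop. Post-processing computes wall shear stress, TAWSS, OSI,
    low-shear vulnerability masks and von Mises wall stress; single-phase
    comparators (Newtonian, power-law, Quemada) run on the same grid for
    two-phase versus single-phase comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
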