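Package: softsim
Title: Viscoelastic Mass-Spring-Damper Soft-Body Simulation with Compliant Constraints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates deformable soft bodies such as soft biological tissue by
    coupling nonlinear viscoelastic mass-spring-damper forces with compliant
    (XPBD-style) position-based constraint projection. Provides mesh generators
    (cube lattice, cantilever beam, icosphere) and readers/writers for OBJ, OFF
    and TetGen meshes; nonlinear spring and displacement-scaled damper force
    models; distance, tetrahedral-volume, closed-surface-volume, overstretch
    and contact constraints with analytic gradients; a Gauss-Seidel projection
    solver with spatial-hash collision detection; and scripted rheometry
    experiments (nonlinearity, creep, stress relaxation, volume preservation,
    crush-recovery stability) on synthetic geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
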