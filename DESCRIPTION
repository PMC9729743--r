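Package: fontanflow
Title: Virtual Surgical Planning of Extracardiac Fontan Conduits by
    Desk-Scale Computational Hemodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds parametric T-shaped and Y-shaped extracardiac-conduit
    geometries for the total cavopulmonary connection (Fontan circulation),
    solves pulsatile incompressible laminar flow through them on a voxelized
    staggered Cartesian grid with a Chorin-style pressure projection, and
    compares candidate designs on four hemodynamic indicators: the
    caval-to-pulmonary pressure gradient, conduit section velocity, energy
    efficiency, and the inferior-vena-cava flow split measured by massless
    Lagrangian particle tracking. Candidate designs are rank-scored on the
    four indicators to select the optimal conduit under rest and
    graded-exercise boundary conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
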