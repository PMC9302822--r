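Package: callusim
Title: Coupled Finite-Element and Fuzzy-Logic Simulation of Secondary Bone
    Fracture Healing in Plated Femora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates secondary (callus-mediated) bone fracture healing in a
    plated diaphyseal bone segment by iterating a daily loop of linear-elastic
    tetrahedral finite-element analysis and Mamdani fuzzy-logic tissue
    differentiation.  A parametric voxel geometry generator builds the
    fractured bone, ellipsoidal callus, plate and screws for two fixation
    mechanisms (locked plate and dynamic compression plate, the latter with
    screw pretension and frictional plate-bone contact).  Per-element
    hydrostatic and distortional strain invariants drive a 19-rule fuzzy
    controller that updates blood perfusion, cartilage and woven-bone
    concentrations; tissue-mixture material properties close the loop.
    Includes mesh readers/writers for Gmsh MSH v4 and VTU, per-day healing
    histories and field snapshots, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
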