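Package: rigidtrack
Title: Marker-Based Rigid-Body Registration, Motion Processing, and
    Static FEM for Mixed-Reality Surgical Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for marker-based optical motion tracking in
    mixed-reality surgical simulation. Provides two-way semi-automatic
    registration of virtual surface models against captured retro-reflective
    markers (least-squares rigid alignment via singular value decomposition),
    generation and parsing of VSK-style tracking-model XML files, offline
    processing of captured pose streams (exponential-map to quaternion
    conversion, unit scaling, single-pole low-pass filtering, occlusion gap
    filling, orientation-flip detection), a critical-force warning monitor,
    a linear-elastic static finite-element solver on 4-node tetrahedra with
    von Mises stress and critical-force sweep, and deterministic synthetic
    fixture generators for all input classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    xml2,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
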