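Package: cif2print
Title: Convert Crystal Structures into Watertight 3D-Printable Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Batch conversion of crystallographic information files (CIF)
    into 3D-printable ball-and-stick models. Parses CIF 1.1 cell parameters,
    symmetry operators and atom sites, applies space-group symmetry to the
    asymmetric unit (optionally packing one unit cell), perceives bonds from
    covalent radii, selects the largest connected molecule or extended-solid
    network, and exports scaled, independently watertight triangle-mesh
    shells as VRML 2.0 indexed face sets (multi-colour printing) and
    binary or ASCII STL. Includes a synthetic CIF fixture generator with
    known ground truth, mesh validation (manifoldness, winding, signed
    volume), and a batch driver with per-file fault isolation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, igraph
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
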