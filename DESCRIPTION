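Package: femurFE
Title: Mechanobiological Finite-Element Simulation of Proximal Femoral Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how proximal femoral geometry (neck-shaft angle and
    anteversion angle) interacts with hip loading during gait to shape femoral
    growth. Provides a parametric all-hexahedral femur mesh generator with a
    layered growth plate, rigid registration and host-mesh (free-form lattice)
    morphing between geometries, a synthetic double-peak hip joint contact
    force generator with nine stance-phase load instances and concentrated
    muscle forces, a small-strain linear-elastic solver for 8-node hexahedra
    with incompatible bending modes, and a mechanobiological growth engine
    based on the osteogenic index (octahedral shear stress promotes, while
    hydrostatic compression inhibits growth) with growth applied as an
    anisotropic eigenstrain along the deflected femoral neck direction.
    Includes measurement of neck-shaft and anteversion angles on arbitrary
    meshes, STL/VTK/Abaqus INP interchange, and a reproducible pipeline for
    geometry-sensitivity experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'geometry.R'
    'mesh-io.R'
    'fe-solver.R'
    'morphing.R'
    'loads.R'
    'growth.R'
    'pipeline.R'
    'cli.R'
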