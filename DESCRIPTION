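Package: molviewr
Title: Headless Molecular Structure Toolkit: PDBx Codecs, Representation
    Geometry and Software Rendering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A headless toolkit for macromolecular structure data. Reads and
    writes the PDBx family of formats (mmCIF/STAR, PDBML, mmJSON, including a
    backbone-only "lite" mmJSON), plus legacy PDB, GRO, MOL2, MDL structure
    files, CCP4 density maps and Gromacs TRR/XTC trajectories. Builds triangle
    meshes for the common molecular representations (VDW, ball-and-stick,
    stick, C-alpha trace, tube, cartoon, rocket, Gaussian coarse surface) with
    level-of-detail scaling, assigns colours by element, group, chain,
    secondary structure or ABEGO class, and renders scenes with a deterministic
    z-buffered rasterizer with per-pixel Phong shading to PNG images and
    animation frame sequences. A small command language and command-line
    scripts drive the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    png,
    grDevices,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
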