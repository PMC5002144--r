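# molviewr

A headless molecular-structure toolkit for R: the computational core of a
molecular viewer, without the viewer. It is aimed at structural
bioinformaticians who need to script the pipeline that interactive viewers
hide — parse a structure or density map, build the polygon geometry of a
representation, colour it, and render publication-style PNG images or
animation frame sequences — entirely from R code or shell scripts, with
bit-reproducible output.

## What it implements

**The PDBx codec family.** mmCIF is a STAR-syntax text format: named
`data_` blocks of categories, each category a table of typed columns.
molviewr parses and writes mmCIF, reads PDBML (the XML serialization of the
same data model), and converts both to and from **mmJSON**, the JSON
rendering in which a block becomes an object of per-category objects of
column arrays — `{"data_XXXX": {"atom_site": {"Cartn_x": [11.1, …], …}}}` —
with numeric tokens as JSON numbers and both `?` (unknown) and `.`
(inapplicable) as `null`. A backbone-only "lite" mmJSON writer keeps one
trace atom per residue (CA for amino acids, P for nucleotides) and a
minimal item whitelist. `compare_compressed_sizes()` reports the
gzip-compressed size reduction `100·(1 − size_mmJSON/size_other)` of mmJSON
against mmCIF and PDBML over a corpus directory.

**Structure model and readers.** All inputs (mmCIF/mmJSON/PDBML, legacy
PDB, GRO, MOL2, MDL; CCP4 density maps; Gromacs TRR and XTC trajectories)
land in shared types: a `molstruct` atom/residue/chain hierarchy with one
or more coordinate models (Å), a `volgrid` axis-ordered scalar grid, and a
`moltraj` frame list. Secondary structure comes from file annotations when
present, else from a backbone-dihedral heuristic; bonds are inferred with a
cell-grid search using the rule
*d ≤ r\_cov(i) + r\_cov(j) + 0.45 Å*. A small selection language
(`chain A and resi 10-20 and not hetero`) addresses atoms. The XTC reader
and writer implement the full Gromacs integer-compression scheme (per-frame
bounds, variable bit-width packing, small-delta run-length encoding); a
coordinate survives a round trip within `1/(2·precision)` nm.

**Representation geometry.** Eight mesh builders — VDW spheres,
ball-and-stick, stick, Cα trace, tube, cartoon (with sheet arrowheads),
rocket, and a Gaussian-density coarse surface — produce indexed triangle
meshes (positions, unit normals, per-vertex RGBA). Backbone sweeps use
Catmull-Rom splines with parallel-transport frames; surfaces use marching
cubes with the standard 256-case table; `lod_params()` scales tessellation
down as atom counts grow so million-atom structures stay tractable.
`contour_volume()` triangulates CCP4 maps at an iso-level, honouring axis
order and triclinic cells.

**Colouring and rendering.** Colour schemes: CPK elements, blue-to-red
group gradient, cycled chain palette, secondary structure, ABEGO backbone
classes, and custom overrides. The renderer is a deterministic z-buffered
software rasterizer with perspective-correct interpolation and per-pixel
Phong shading — per channel
`c·(k_a + k_d·max(N·L,0)) + 255·k_s·max(R·V,0)^s` — writing 8-bit RGBA
PNGs; `render_frames()` renders a trajectory as a numbered frame sequence
with the camera fixed on frame one (stitch to video with any external
encoder).

**Command language.** A closed, safe verb set (`load`, `fetch`, `show`,
`hide`, `color`, `select`, `snapshot`, `movie`, `set`), PyMOL-style
argument order, the `molmil.loadPDB('1crn')` function-call form, and
URL-fragment extraction (`…#fetch toy;show cartoon`). `inst/cli/molviewr`
is an Rscript front end with `convert`, `sizestats`, `info`, `render`,
`movie`, `run`, `exec` and `fixtures` subcommands.

## Worked example

```r
library(molviewr)

st <- build_structure(parse_mmcif(
  path = system.file("extdata", "mirror", "toy.cif", package = "molviewr")))
st
#> <molstruct> toy: 48 atoms, 16 residues, 1 chains, 1 model(s)
table(st$residues$ss)
#>  coil helix
#>     4    12

mesh <- build_cartoon(st, colors = apply_scheme(st, scheme = "ss"))
mesh
#> <molmesh> 3856 vertices, 7680 triangles
img <- rasterize(new_scene(mesh), auto_fit(mesh, 320, 240))
img
#> <molimage> 320 x 240, 2.8% covered
write_png(img, "toy.png")

f <- focus_target(st, select_atoms(st, "resi 5-8 and name CA"))
#> focus centre (5.62, 5.97, -4.96), radius 3.12 A

fx <- make_random_walk_trajectory(n_atoms = 48, n_frames = 3, seed = 7)
back <- read_xtc(bytes = fx$xtc)
max(abs(back$frames[[3]]$coords - fx$traj$frames[[3]]$coords))
#> 0.0050  # Angstrom; the quantization bound at precision 1000 is 0.005
```

The 16-residue entry is a packaged ideal poly-alanine helix; the dihedral
heuristic marks its 12 interior residues helix, the cartoon builder sweeps
an elliptical ribbon over the spline, and the render covers 2.8 % of a
320×240 frame. The same pipeline runs from the command language:

```r
run_script(c("fetch toy", "show cartoon", "color chain",
             "snapshot toy.png, width=320, height=240"))
```

Or from the shell: `inst/cli/molviewr render toy.cif --repr cartoon -o toy.png`.

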