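---
title: "molviewr: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{molviewr: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molviewr)
```

molviewr is the computational core of a molecular viewer packaged as a
headless toolkit: format codecs, a structure model, representation
geometry, colouring, and a deterministic software renderer. This vignette
explains the models it implements, the numerical and design choices made
where the problem left them open, and what the test fixtures do and do not
demonstrate.

## The STAR data model and the codec family

Everything text-based rests on one in-memory model: a *block* (named after
its `data_` header) holds ordered *categories*; a category is an ordered
map of item keywords to equal-length columns; a cell is an integer, a
real, a text string, or null. The codecs (mmCIF reader/writer, PDBML
reader, mmJSON reader/writer) are total maps onto this model, which makes
cross-codec equality a testable property: one fixture entry serialized
three ways must parse to the identical model, and therefore to identical
mmJSON text.

Decisions that shape the model:

* **Null collapsing.** mmCIF distinguishes `?` (unknown) from `.`
  (inapplicable); JSON has only `null`. Both map to null, and nulls are
  re-serialized as `?`. The distinction is deliberately lost — the data
  model carries one null, and the mmCIF writer is documented as such.
* **Numeric coercion.** An unquoted token becomes a number only when it
  *fully* matches an integer or decimal/scientific literal. Zero-padded
  tokens such as `007` stay text: they are almost always author-assigned
  identifiers, and coercing them would corrupt round trips. Quoted tokens
  are always text, so a file can force `"123"` to remain a string.
* **Order preservation.** Categories and items keep source order; mmJSON
  keys follow insertion order. This makes diffs reproducible and the
  cross-codec identity exact rather than equal-up-to-reordering.
* **Scope.** `save_` frames, dictionaries and `global_` blocks are
  rejected with explicit errors: this is a coordinate-file codec, and
  coordinate files never carry them.
* **Empty tables.** A zero-row category is representable in mmJSON
  (`"x": []`) but not in mmCIF (a `loop_` with tags and no values is
  ambiguous to any reader); the writer therefore omits empty categories.

The writer chooses the lightest safe quoting: bare token where possible,
single then double quotes, and a semicolon text field when a value
contains a newline or both quote characters. A value is also quoted
whenever re-parsing it bare would change its type — that single rule is
what makes `parse ∘ write` the identity on the model.

The "lite" mmJSON variant keeps `atom_site` rows whose atom id is CA (for
amino acids) or P (nucleotides), the eleven items needed to draw and label
a backbone trace, and passes through `struct_conf` and
`struct_sheet_range`. The item whitelist is this package's own choice of
"minimal but sufficient for a backbone cartoon".

`compare_compressed_sizes()` gzips the three serializations per corpus
entry (level 6 by default, exposed as a flag) and reports
`100 · (1 − size_mmJSON / size_other)`. On the synthetic all-backbone
corpus used by `scripts/acceptance.R` the reduction is measured at run
time; archive-scale mixed-content entries compress differently, so those
numbers characterize the corpus, not the archive.

## Structure model

Readers produce a flat atom table plus residue and chain tables and a list
of per-model coordinate matrices — the natural R shape for this data, and
one that keeps selection and colouring vectorized. Invariants: every model
has the same atom count; residues are contiguous runs in file order;
every atom has a non-empty element (taken from `type_symbol`/columns 77-78
when present, else inferred from the atom name).

* **Alternate locations** are reduced to one conformer per atom site by
  keeping the highest occupancy, alphabetically first on ties. This is the
  convention most viewers apply silently; it is applied identically across
  readers so the hierarchy invariant (atoms in = atoms kept) is testable.
* **Secondary structure.** File annotations always win. Without them, a
  residue is *helix* when (φ, ψ) ∈ (−100°, −30°) × (−80°, −5°) for itself
  and both neighbours, *sheet* when φ ∈ (−180°, −80°) and ψ ∈ (80°, 180°]
  ∪ [−180°, −170°) likewise, else *coil*. The windows are generous
  Ramachandran-region boxes; the three-residue requirement suppresses
  single-residue flickers. This is a display heuristic, not DSSP: it uses
  no hydrogen-bond geometry and will under-call distorted strands.
* **Bonds.** Atoms bond when their distance lies in
  (0.4 Å, r₁ + r₂ + 0.45 Å], with Cordero single-bond covalent radii.
  A uniform cell grid (cell edge = maximum cutoff) restricts the search to
  27 neighbouring cells, making cost near-linear; the test suite asserts
  exact agreement with an O(n²) oracle. Inter-residue bonds are limited to
  adjacent residues of one chain plus S–S pairs up to 2.5 Å, which
  prevents spurious long-range bonds in packed crystals. Explicit bond
  blocks (MOL2, MDL) override inference.
* **Selections** use a recursive-descent parser over the grammar given in
  `?select_atoms`, with `and`/`or`/`not` and parentheses; the algebra (De
  Morgan, complements) is property-tested. `resi` ranges are inclusive
  author numbering, matching what users read off a structure.

## Binary formats

CCP4 maps: byte order is taken from the MACHST stamp, falling back to mode
plausibility; modes 2 (float32), 1 (int16) and 0 (int8) are read, all
widened to doubles. The grid keeps its file axis order; Cartesian
placement happens at contouring time through the fractional-to-Cartesian
cell matrix, so triclinic cells and permuted axis orders are handled in
one code path (and the permutation-invariance of the resulting mesh is a
test).

TRR frames are XDR big-endian with per-block byte sizes in the header;
single/double precision is detected from the box or coordinate block
size. Velocities and forces are skipped — the toolkit consumes positions.

The XTC coordinate codec is implemented in full: coordinates are scaled by
the precision and rounded to integers; per-frame minima/maxima bound the
large-integer bit width; runs of atoms whose deltas fit the adaptive
"small" magic-number table are packed at a narrower width with a
run-length code, with the water-pair swap of the reference scheme.
Arithmetic uses doubles throughout (exact for the ≤ 2²⁴ magnitudes the
format guarantees), avoiding 32-bit overflow. The writer exists so the
reader can be tested end-to-end without external files; additionally the
test suite decodes a small frozen reference file produced by an
independent implementation, pinning the bit-level layout rather than just
writer/reader consistency. The round-trip error bound `1/(2·precision)` nm
is asserted across precisions 100, 1000 and 10000.

## Representation geometry

All builders emit one mesh type: positions, unit normals, per-vertex RGBA
and 32-bit-capable triangle indices, checked by a shared validator.
Builders are pure functions — same structure, selection and detail give a
bit-identical mesh — which is what makes image-level determinism possible
downstream.

The level-of-detail policy is piecewise constant in atom count
(≤10⁴ atoms: icosphere subdivision 3, 16 cylinder segments, 16 spline
samples/residue, 0.8 Å surface grid; ≤10⁵: 2/12/8/1.2; ≤10⁶: 1/8/4/2.0;
above: 0/6/2/3.0). The thresholds are this package's stated policy: each
step roughly caps sphere-vertex counts near 10⁶ at the transition points,
degrading tessellation rather than refusing to draw.

Dimensions (tube radius 0.3 Å, helix ribbon 1.4 × 0.25 Å, sheet ribbon
1.2 × 0.25 Å with an 1.8 Å arrowhead tapering to a point over the last
strand residue, rocket cylinder 1.2 Å, ball 0.25 Å, bond 0.15 Å, stick
0.25 Å) are conventional viewer proportions, fixed as constants so images
are stable across releases. Backbone sweeps sample a Catmull-Rom spline
(endpoint-duplicated, so the curve passes through every trace atom; the
closed-form midpoint `(−P₀+9P₁+9P₂−P₃)/16` is asserted) and transport the
cross-section frame by projecting the previous normal off each new
tangent — parallel transport rather than Frenet frames, because Frenet
frames flip at inflection points and produce twisted ribbons. Nucleic
chains are swept as tubes through P atoms; no base ladders.

Surfaces use marching cubes with the standard 256-case Lorensen–Cline
table and linear interpolation along cell edges; vertices are
deduplicated per grid edge, so the mesh is watertight whenever the
iso-level is not crossed on the grid boundary. Ambiguous face cases are
resolved by the standard table itself (no asymptotic decider); on the
smooth Gaussian fields used here that choice never produced a hole, and
watertightness is asserted for every generated surface. The coarse
molecular surface is the iso-0.5 contour of
ρ(x) = Σᵢ exp(−|x−xᵢ|²/2σ²) with σ = 0.6·spacing + 0.9 Å — the width
scales with the grid so coarser grids blur rather than alias — on a grid
padded 4 Å (boundary density ≲ 0.34 even at the coarsest spacing, safely
below the level). Normals come from the interpolated density gradient,
negated to point outward.

## Renderer

The camera is fitted by placing the eye on the −z axis through the
centroid at distance `r/sin(fov/2) · 1.05` (5 % margin), near/far at
distance ∓ 1.1 r (near clamped positive), so the bounding sphere is inside
the frustum by construction — asserted per vertex in tests. Rasterization
is textbook: perspective projection, per-triangle bounding-box scan at
pixel centres, barycentric coverage (winding-independent), a z-buffer on
perspective-correct depth, and attributes (normals, colours) interpolated
perspective-correctly. No back-face culling; fragments whose interpolated
normal faces away from the eye are flipped, which shades open tubes and
arrowhead interiors correctly. Shading is Phong per pixel:
`c·(k_a + k_d·max(N·L,0)) + 255·k_s·max(R·V,0)^s` with `R = 2(N·L)N − L`,
a single directional headlight along the view axis, and default material
(0.25, 0.65, 0.35, shininess 32) exposed through `new_material()` and the
command language's `set`.

Determinism is a contract: integer pixel operations, `round()` (R's
half-to-even) before quantization, no antialiasing by default, and a PNG
encoder with fixed settings — two renders of one scene are byte-identical,
and the test suite compares files, not pixels. Alpha below 255 renders
opaque with a warning; transparency sorting is out of scope.

## Synthetic fixtures: what they demonstrate

The generators produce every input kind the toolkit reads, deterministically
under a seed: ideal poly-alanine backbones placed by sequential
internal-coordinate (NeRF-style) construction with standard bond geometry
(N–CA 1.458, CA–C 1.525, C–N 1.329 Å; the default φ=−57°, ψ=−47° gives
3.8 Å Cα spacing and 1.5 Å rise, both asserted); a matched
mmCIF/PDBML/mmJSON triple; Gaussian density maps with analytically known
iso-contours (half-max radius σ√(2 ln 2)); and Gaussian random-walk
trajectories with TRR/XTC bytes. Random STAR blocks drive the codec
property tests with mixed types, nulls, quotes and zero-padded
identifiers.

What passing these tests shows: the codecs, codecs' error paths, geometry
counts, analytic radii and round-trip bounds are correct on clean,
well-formed input. What they do not show: robustness to the PDB archive's
full variety (insertion codes in anarchic order, microheterogeneity,
multi-kilobyte text fields, non-standard PDBML), realistic force-field
dynamics, or sequence realism. The fixtures emulate structure, not
biology.

## Problem sizes

The default test suite and the acceptance script are sized for a single
CPU: 200 random blocks per codec identity check, bond oracles at n ≤ 100,
500 random triangle pairs for the depth-test property, 320×240 and smaller
rendered frames, trajectories of tens of atoms and a handful of frames.
All scale linearly if larger runs are wanted; the sizes are stated in the
scripts themselves.

## Known limitations

No mmCIF dictionary validation or save frames; no DSSP-grade secondary
structure; no MSMS or solvent-accessible surfaces (the coarse Gaussian
surface is the only surface mode); no symmetry/biological-assembly
expansion; MDL V3000 and multi-record SDF iteration are out of scope; the
myPresto trajectory format has no public specification and is left as a
reader extension point; rendering has no shadows, transparency or GPU
path. The command language is a closed verb set by design — it executes no
host-language code.
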