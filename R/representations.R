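#' Level-of-detail parameters for an atom count
#'
#' Piecewise-constant, monotonically non-increasing detail policy: small
#' structures get high-quality geometry, gigantic ones progressively
#' coarser tessellation so million-atom entries stay drawable.
#'
#' @param atom_count number of atoms to be drawn (>= 0).
#' @return list with `sphere_subdiv` (icosphere level 0-3), `cyl_segments`
#'   (radial segments 4-16), `spline_samples` (per residue 2-16) and
#'   `surface_spacing` (grid spacing, Angstrom).
#' @export
lod_params <- function(atom_count) {
  stopifnot(atom_count >= 0)
  if (atom_count <= 1e4) list(sphere_subdiv = 3L, cyl_segments = 16L,
                              spline_samples = 16L, surface_spacing = 0.8)
  else if (atom_count <= 1e5) list(sphere_subdiv = 2L, cyl_segments = 12L,
                                   spline_samples = 8L, surface_spacing = 1.2)
  else if (atom_count <= 1e6) list(sphere_subdiv = 1L, cyl_segments = 8L,
                                   spline_samples = 4L, surface_spacing = 2.0)
  else list(sphere_subdiv = 0L, cyl_segments = 6L, spline_samples = 2L,
            surface_spacing = 3.0)
}

GREY <- c(200L, 200L, 200L, 255L)

# per-atom colour lookup: matrix row, or a constant
atom_color <- function(colors, i) {
  if (is.null(colors)) return(GREY)
  if (is.matrix(colors)) as.integer(colors[i, ]) else as.integer(colors)
}

#' Van der Waals sphere representation
#'
#' One icosphere per selected atom at its Bondi van der Waals radius.
#'
#' @param structure a `molstruct`.
#' @param selection selection (expression, `molsel`, indices or `NULL`).
#' @param detail [lod_params()] list.
#' @param colors per-atom RGBA matrix (`n_atoms` rows) or single RGBA.
#' @param model model index.
#' @return a `molmesh`.
#' @export
build_vdw <- function(structure, selection = NULL,
                      detail = lod_params(n_atoms(structure)),
                      colors = NULL, model = 1L) {
  idx <- as_atom_indices(structure, selection)
  if (!length(idx)) stop("empty selection")
  co <- structure$coords[[model]]
  rad <- vdw_radius(structure$atoms$element)
  merge_meshes(lapply(idx, function(i)
    sphere_mesh(co[i, ], rad[[i]], detail$sphere_subdiv, atom_color(colors, i))))
}

BALL_RADIUS <- 0.25
BOND_RADIUS <- 0.15
STICK_RADIUS <- 0.25
TRACE_RADIUS <- 0.3
CA_TRACE_CUTOFF <- 4.5

#' Ball-and-stick representation
#'
#' Spheres of 0.25 Angstrom at atoms plus 0.15 Angstrom bond cylinders split
#' at the bond midpoint so each half carries its atom's colour.
#'
#' @inheritParams build_vdw
#' @return a `molmesh`.
#' @export
build_ball_stick <- function(structure, selection = NULL,
                             detail = lod_params(n_atoms(structure)),
                             colors = NULL, model = 1L) {
  idx <- as_atom_indices(structure, selection)
  if (!length(idx)) stop("empty selection")
  co <- structure$coords[[model]]
  meshes <- lapply(idx, function(i)
    sphere_mesh(co[i, ], BALL_RADIUS, detail$sphere_subdiv,
                atom_color(colors, i)))
  bonds <- selected_bonds(structure, idx)
  if (!nrow(bonds)) {
    warning("no bonds within selection: spheres only")
  } else {
    for (r in seq_len(nrow(bonds))) {
      a <- bonds[r, 1L]; b <- bonds[r, 2L]
      mid <- (co[a, ] + co[b, ]) / 2
      meshes[[length(meshes) + 1L]] <-
        cylinder_mesh(co[a, ], mid, BOND_RADIUS, detail$cyl_segments,
                      atom_color(colors, a))
      meshes[[length(meshes) + 1L]] <-
        cylinder_mesh(mid, co[b, ], BOND_RADIUS, detail$cyl_segments,
                      atom_color(colors, b))
    }
  }
  merge_meshes(meshes)
}

#' Stick representation
#'
#' Bond cylinders of 0.25 Angstrom with sphere caps at the atoms. With no
#' bonds in the selection an empty mesh is returned with a warning.
#'
#' @inheritParams build_vdw
#' @return a `molmesh`.
#' @export
build_stick <- function(structure, selection = NULL,
                        detail = lod_params(n_atoms(structure)),
                        colors = NULL, model = 1L) {
  idx <- as_atom_indices(structure, selection)
  if (!length(idx)) stop("empty selection")
  co <- structure$coords[[model]]
  bonds <- selected_bonds(structure, idx)
  if (!nrow(bonds)) {
    warning("no bonds within selection: empty stick mesh")
    return(new_mesh())
  }
  meshes <- list()
  for (r in seq_len(nrow(bonds))) {
    a <- bonds[r, 1L]; b <- bonds[r, 2L]
    mid <- (co[a, ] + co[b, ]) / 2
    meshes[[length(meshes) + 1L]] <-
      cylinder_mesh(co[a, ], mid, STICK_RADIUS, detail$cyl_segments,
                    atom_color(colors, a))
    meshes[[length(meshes) + 1L]] <-
      cylinder_mesh(mid, co[b, ], STICK_RADIUS, detail$cyl_segments,
                    atom_color(colors, b))
  }
  for (i in sort(unique(as.vector(bonds))))
    meshes[[length(meshes) + 1L]] <-
      sphere_mesh(co[i, ], STICK_RADIUS, max(0L, detail$sphere_subdiv - 1L),
                  atom_color(colors, i))
  merge_meshes(meshes)
}

# bonds with both ends inside the selection
selected_bonds <- function(structure, idx) {
  bonds <- structure_bonds(structure)
  if (!nrow(bonds)) return(bonds)
  keep <- bonds[, 1L] %in% idx & bonds[, 2L] %in% idx
  bonds[keep, , drop = FALSE]
}

#' C-alpha trace representation
#'
#' Cylinders of 0.3 Angstrom joining consecutive CA atoms closer than
#' 4.5 Angstrom (chain breaks leave gaps).
#'
#' @inheritParams build_vdw
#' @return a `molmesh`.
#' @export
build_ca_trace <- function(structure, selection = NULL,
                           detail = lod_params(n_atoms(structure)),
                           colors = NULL, model = 1L) {
  idx <- as_atom_indices(structure, selection)
  co <- structure$coords[[model]]
  at <- structure$atoms
  meshes <- list()
  for (ci in seq_len(nrow(structure$chains))) {
    rix <- which(structure$residues$chain_index == ci)
    cas <- integer(0)
    for (ri in rix) {
      k <- which(at$residue_index == ri & at$name == "CA")
      k <- intersect(k, idx)
      if (length(k)) cas <- c(cas, k[[1L]])
    }
    if (length(cas) < 2L) next
    for (q in seq_len(length(cas) - 1L)) {
      a <- cas[[q]]; b <- cas[[q + 1L]]
      if (sqrt(sum((co[a, ] - co[b, ])^2)) > CA_TRACE_CUTOFF) next
      mid <- (co[a, ] + co[b, ]) / 2
      meshes[[length(meshes) + 1L]] <-
        cylinder_mesh(co[a, ], mid, TRACE_RADIUS, detail$cyl_segments,
                      atom_color(colors, a))
      meshes[[length(meshes) + 1L]] <-
        cylinder_mesh(mid, co[b, ], TRACE_RADIUS, detail$cyl_segments,
                      atom_color(colors, b))
    }
  }
  if (!length(meshes)) {
    warning("no CA trace segments in selection")
    return(new_mesh())
  }
  merge_meshes(meshes)
}

# trace atoms (CA or P) per chain, restricted to a selection;
# returns list of lists with atom indices and residue indices
chain_traces <- function(structure, idx) {
  at <- structure$atoms
  out <- list()
  for (ci in seq_len(nrow(structure$chains))) {
    tname <- if (structure$chains$moltype[ci] == "nucleic") "P" else "CA"
    rix <- which(structure$residues$chain_index == ci)
    atoms <- integer(0); resi <- integer(0)
    for (ri in rix) {
      k <- which(at$residue_index == ri & at$name == tname)
      k <- intersect(k, idx)
      if (length(k)) { atoms <- c(atoms, k[[1L]]); resi <- c(resi, ri) }
    }
    out[[length(out) + 1L]] <- list(chain = ci, atoms = atoms, resi = resi)
  }
  out
}

TUBE_RADIUS <- 0.3
HELIX_W <- 1.4; HELIX_H <- 0.25
SHEET_W <- 1.2; SHEET_H <- 0.25
ARROW_W <- 1.8

#' Tube representation
#'
#' Circular cross-section of radius 0.3 Angstrom swept along the
#' Catmull-Rom backbone spline with parallel-transport frames. A 10-residue
#' chain with `spline_samples = s` produces `9 s + 1` rings.
#'
#' @inheritParams build_vdw
#' @return a `molmesh`.
#' @export
build_tube <- function(structure, selection = NULL,
                       detail = lod_params(n_atoms(structure)),
                       colors = NULL, model = 1L) {
  sweep_representation(structure, selection, detail, colors, model,
                       style = "tube")
}

#' Cartoon representation
#'
#' Cross-section chosen by secondary structure: coil is a 0.3 Angstrom
#' circle, helix a 1.4 x 0.25 Angstrom ribbon, sheet a 1.2 x 0.25 ribbon
#' ending in an arrowhead 1.8 Angstrom wide that tapers to a point over the
#' last residue of the strand. Nucleic-acid chains are drawn as a tube
#' through the P trace.
#'
#' @inheritParams build_vdw
#' @return a `molmesh`.
#' @export
build_cartoon <- function(structure, selection = NULL,
                          detail = lod_params(n_atoms(structure)),
                          colors = NULL, model = 1L) {
  sweep_representation(structure, selection, detail, colors, model,
                       style = "cartoon")
}

#' Rocket representation
#'
#' Helices become single cylinders of radius 1.2 Angstrom from the first to
#' the last helix CA, capped by a cone; everything else is drawn as tube.
#'
#' @inheritParams build_vdw
#' @return a `molmesh`.
#' @export
build_rocket <- function(structure, selection = NULL,
                         detail = lod_params(n_atoms(structure)),
                         colors = NULL, model = 1L) {
  idx <- as_atom_indices(structure, selection)
  co <- structure$coords[[model]]
  meshes <- list()
  any_chain <- FALSE
  for (tr in chain_traces(structure, idx)) {
    if (length(tr$atoms) < 2L) {
      if (length(tr$atoms)) warning("chain with < 2 trace atoms skipped")
      next
    }
    any_chain <- TRUE
    ss <- structure$residues$ss[tr$resi]
    runs <- rle(ss == "helix")
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (g in seq_along(runs$values)) {
      seg <- starts[[g]]:ends[[g]]
      if (runs$values[[g]] && length(seg) >= 2L) {
        p0 <- co[tr$atoms[[seg[1L]]], ]
        p1 <- co[tr$atoms[[seg[length(seg)]]], ]
        axis <- p1 - p0
        len <- sqrt(sum(axis^2))
        tipbase <- if (len > 2.5) p1 - axis / len * 2 else p0 + axis * 0.5
        col <- atom_color(colors, tr$atoms[[seg[1L]]])
        meshes[[length(meshes) + 1L]] <-
          cylinder_mesh(p0, tipbase, 1.2, detail$cyl_segments, col)
        meshes[[length(meshes) + 1L]] <-
          cone_mesh(tipbase, p1, 1.8, detail$cyl_segments, col)
      } else if (length(seg) >= 2L) {
        sub <- tr$atoms[seg]
        meshes[[length(meshes) + 1L]] <-
          sweep_mesh(co[sub, , drop = FALSE], rep("coil", length(seg)),
                     detail, vapply(sub, function(i)
                       atom_color(colors, i), integer(4)))
      }
    }
  }
  if (!any_chain) {
    warning("no polymer trace for rocket representation")
    return(new_mesh())
  }
  merge_meshes(meshes)
}

sweep_representation <- function(structure, selection, detail, colors, model,
                                 style) {
  idx <- as_atom_indices(structure, selection)
  meshes <- list()
  co <- structure$coords[[model]]
  any_chain <- FALSE
  for (tr in chain_traces(structure, idx)) {
    if (length(tr$atoms) < 2L) {
      if (length(tr$atoms)) warning("chain with < 2 trace atoms skipped")
      next
    }
    any_chain <- TRUE
    ss <- if (style == "cartoon") structure$residues$ss[tr$resi]
          else rep("coil", length(tr$atoms))
    cols <- vapply(tr$atoms, function(i) atom_color(colors, i), integer(4))
    meshes[[length(meshes) + 1L]] <-
      sweep_mesh(co[tr$atoms, , drop = FALSE], ss, detail, cols)
  }
  if (!any_chain) {
    warning("no polymer trace atoms in selection")
    return(new_mesh())
  }
  merge_meshes(meshes)
}

# Sweep an (optionally ss-shaped) cross-section along the spline through the
# trace points. cols: 4 x n_res integer matrix of per-residue colours.
sweep_mesh <- function(trace, ss, detail, cols) {
  nres <- nrow(trace)
  s <- detail$spline_samples
  path <- spline_path(trace, s)
  np <- nrow(path)
  # per-sample residue parameter in [1, nres]
  tpar <- 1 + (seq_len(np) - 1L) / s
  ri <- pmin(floor(tpar), nres)        # residue the sample starts in
  frac <- tpar - ri
  wh <- section_profile(ss, ri, frac)
  frames <- transport_frames(path)
  seg <- detail$cyl_segments
  ang <- 2 * pi * (seq_len(seg) - 1L) / seg
  ca <- cos(ang); sa <- sin(ang)
  pos <- matrix(0, np * seg, 3L)
  nrm <- matrix(0, np * seg, 3L)
  colm <- matrix(0L, np * seg, 4L)
  for (i in seq_len(np)) {
    a <- max(wh$w[i] / 2, 1e-4); b <- max(wh$h[i] / 2, 1e-4)
    Nv <- frames$normal[i, ]; Bv <- frames$binormal[i, ]
    ring <- outer(ca * a, Nv) + outer(sa * b, Bv)
    rn <- outer(ca / a, Nv) + outer(sa / b, Bv)
    rn <- rn / sqrt(rowSums(rn^2))
    rows <- ((i - 1L) * seg + 1L):(i * seg)
    pos[rows, ] <- sweep(ring, 2L, path[i, ], `+`)
    nrm[rows, ] <- rn
    colr <- cols[, min(nres, ri[i] + as.integer(frac[i] > 0.5))]
    colm[rows, ] <- matrix(rep(colr, each = seg), seg, 4L)
  }
  tri <- matrix(0L, 2L * seg * (np - 1L), 3L)
  row <- 1L
  for (i in seq_len(np - 1L)) {
    b0 <- (i - 1L) * seg; b1 <- i * seg
    j <- seq_len(seg); j2 <- c(seq_len(seg - 1L) + 1L, 1L)
    tri[row:(row + seg - 1L), ] <- cbind(b0 + j, b0 + j2, b1 + j)
    tri[(row + seg):(row + 2L * seg - 1L), ] <- cbind(b0 + j2, b1 + j2, b1 + j)
    row <- row + 2L * seg
  }
  new_mesh(pos, nrm, colm, tri)
}

# Cross-section width/height per path sample. Handles the sheet arrowhead:
# the last residue of each sheet run starts at ARROW_W and tapers to zero.
section_profile <- function(ss, ri, frac) {
  nres <- length(ss)
  base_w <- ifelse(ss == "helix", HELIX_W, ifelse(ss == "sheet", SHEET_W,
                   2 * TUBE_RADIUS))
  base_h <- ifelse(ss == "coil", 2 * TUBE_RADIUS,
                   ifelse(ss == "helix", HELIX_H, SHEET_H))
  # identify the final residue of each sheet run
  arrow_last <- rep(FALSE, nres)
  r <- rle(ss)
  ends <- cumsum(r$lengths)
  arrow_last[ends[r$values == "sheet"]] <- TRUE
  n <- length(ri)
  w <- numeric(n); h <- numeric(n)
  for (i in seq_len(n)) {
    a <- ri[i]; f <- frac[i]
    b <- min(a + 1L, nres)
    if (b > a && arrow_last[b]) {
      # segment leading into the strand's final residue: widen then taper
      w[i] <- ARROW_W * (1 - f)
      h[i] <- SHEET_H
    } else if (arrow_last[a] && f == 0) {
      w[i] <- 0           # arrow tip at the final trace point
      h[i] <- SHEET_H
    } else {
      w[i] <- base_w[a] * (1 - f) + base_w[b] * f
      h[i] <- base_h[a] * (1 - f) + base_h[b] * f
    }
  }
  list(w = w, h = h)
}
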