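#' @title Triangle meshes
#' @description
#' A `molmesh` is the output of every representation builder: vertex
#' positions (Angstrom), unit normals, per-vertex RGBA colours (0-255) and a
#' triangle index matrix. Indices are plain R integers, so meshes well
#' beyond 65,536 vertices are supported (the equivalent of 32-bit element
#' indices).
#' @name molmesh
NULL

#' Construct a mesh
#' @param positions N x 3 numeric matrix (Angstrom).
#' @param normals N x 3 numeric matrix of unit vectors.
#' @param colors N x 4 integer matrix (RGBA, 0-255) or a single RGBA vector
#'   recycled to all vertices.
#' @param triangles M x 3 integer matrix of 1-based vertex indices.
#' @return an object of class `molmesh`.
#' @export
new_mesh <- function(positions = matrix(0, 0L, 3L),
                     normals = matrix(0, 0L, 3L),
                     colors = matrix(0L, 0L, 4L),
                     triangles = matrix(0L, 0L, 3L)) {
  n <- nrow(positions)
  if (is.vector(colors) && length(colors) == 4L)
    colors <- matrix(rep(as.integer(colors), each = n), n, 4L)
  structure(list(positions = positions, normals = normals,
                 colors = colors, triangles = triangles),
            class = "molmesh")
}

#' @export
print.molmesh <- function(x, ...) {
  cat(sprintf("<molmesh> %d vertices, %d triangles\n",
              nrow(x$positions), nrow(x$triangles)))
  invisible(x)
}

#' Validate mesh invariants
#'
#' Checks index bounds, unit normals (|n| = 1 within 1e-6) and absence of
#' non-finite values; shared by every builder's tests.
#'
#' @param mesh a `molmesh`.
#' @return `TRUE`, or a character description of the violation.
#' @export
mesh_validate <- function(mesh) {
  n <- nrow(mesh$positions)
  if (nrow(mesh$normals) != n) return("normals/positions length mismatch")
  if (nrow(mesh$colors) != n) return("colors/positions length mismatch")
  if (any(!is.finite(mesh$positions))) return("non-finite positions")
  if (any(!is.finite(mesh$normals))) return("non-finite normals")
  if (n > 0L) {
    len <- sqrt(rowSums(mesh$normals^2))
    if (any(abs(len - 1) > 1e-6)) return("non-unit normals")
  }
  if (nrow(mesh$triangles)) {
    if (min(mesh$triangles) < 1L || max(mesh$triangles) > n)
      return("triangle index out of bounds")
  }
  if (any(mesh$colors < 0L | mesh$colors > 255L)) return("colour out of range")
  TRUE
}

#' Merge meshes by concatenation with index offsetting
#' @param meshes list of `molmesh` objects.
#' @return a single `molmesh`.
#' @export
merge_meshes <- function(meshes) {
  meshes <- meshes[vapply(meshes, function(m) nrow(m$positions) > 0L, TRUE)]
  if (!length(meshes)) return(new_mesh())
  offs <- cumsum(c(0L, vapply(meshes, function(m) nrow(m$positions), 0L)))
  new_mesh(
    do.call(rbind, lapply(meshes, `[[`, "positions")),
    do.call(rbind, lapply(meshes, `[[`, "normals")),
    do.call(rbind, lapply(meshes, `[[`, "colors")),
    do.call(rbind, lapply(seq_along(meshes), function(i)
      meshes[[i]]$triangles + offs[[i]])))
}

# unit icosahedron vertices/faces (golden-ratio construction)
icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(v = v, f = f)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected to the sphere: `20 * 4^subdiv` triangles
#' and `10 * 4^subdiv + 2` vertices, radial normals.
#'
#' @param center 3-vector (Angstrom).
#' @param radius sphere radius (> 0).
#' @param subdiv subdivision level 0-3.
#' @param color RGBA vector.
#' @return a `molmesh`.
#' @export
sphere_mesh <- function(center = c(0, 0, 0), radius = 1, subdiv = 2L,
                        color = c(200L, 200L, 200L, 255L)) {
  stopifnot(radius > 0, subdiv >= 0L, subdiv <= 3L)
  tmpl <- icosphere_template(as.integer(subdiv))
  pos <- sweep(tmpl$v * radius, 2L, center, `+`)
  new_mesh(pos, tmpl$v, color, tmpl$f)
}

# cached unit icospheres per subdivision level
icosphere_env <- new.env(parent = emptyenv())
icosphere_template <- function(subdiv) {
  key <- as.character(subdiv)
  if (!is.null(icosphere_env[[key]])) return(icosphere_env[[key]])
  ico <- icosahedron()
  v <- ico$v; f <- ico$f
  for (s in seq_len(subdiv)) {
    edge_cache <- new.env(parent = emptyenv())
    midpoint <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      hit <- edge_cache[[k]]
      if (!is.null(hit)) return(hit)
      m <- v[a, ] + v[b, ]
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      idx <- nrow(v)
      edge_cache[[k]] <- idx
      idx
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1L]; b <- f[i, 2L]; cc <- f[i, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[(4L * i - 3L):(4L * i), ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  out <- list(v = v, f = f)
  icosphere_env[[key]] <- out
  out
}

#' Cylinder mesh (open tube)
#'
#' `2 * segments` vertices and `2 * segments` triangles; normals radial to
#' the axis. Optional spherical caps are separate spheres (see
#' [build_stick()]).
#'
#' @param p0,p1 axis end points (must differ).
#' @param radius cylinder radius.
#' @param segments radial segment count (4-16).
#' @param color RGBA vector, or a 2-row matrix for per-end colours.
#' @return a `molmesh`.
#' @export
cylinder_mesh <- function(p0, p1, radius = 0.25, segments = 8L,
                          color = c(200L, 200L, 200L, 255L)) {
  axis <- p1 - p0
  len <- sqrt(sum(axis^2))
  if (len < 1e-9) stop("degenerate cylinder axis: p0 == p1")
  axis <- axis / len
  u <- perpendicular_unit(axis)
  w <- vcross(axis, u)
  ang <- 2 * pi * (seq_len(segments) - 1L) / segments
  ring_n <- outer(cos(ang), u) + outer(sin(ang), w)  # unit radial normals
  ring0 <- sweep(ring_n * radius, 2L, p0, `+`)
  ring1 <- sweep(ring_n * radius, 2L, p1, `+`)
  pos <- rbind(ring0, ring1)
  nrm <- rbind(ring_n, ring_n)
  s <- segments
  i <- seq_len(s); j <- c(seq_len(s - 1L) + 1L, 1L)
  tri <- rbind(cbind(i, j, i + s), cbind(j, j + s, i + s))
  if (is.matrix(color)) {
    cols <- rbind(matrix(rep(as.integer(color[1L, ]), each = s), s, 4L),
                  matrix(rep(as.integer(color[2L, ]), each = s), s, 4L))
  } else cols <- color
  new_mesh(pos, nrm, cols, tri)
}

#' Cone mesh
#' @param base base-centre 3-vector; `apex` tip 3-vector.
#' @param apex cone tip.
#' @param radius base radius.
#' @param segments radial segments.
#' @param color RGBA.
#' @return a `molmesh` (open base).
#' @export
cone_mesh <- function(base, apex, radius, segments = 8L,
                      color = c(200L, 200L, 200L, 255L)) {
  axis <- apex - base
  len <- sqrt(sum(axis^2))
  if (len < 1e-9) stop("degenerate cone axis")
  axis <- axis / len
  u <- perpendicular_unit(axis)
  w <- vcross(axis, u)
  ang <- 2 * pi * (seq_len(segments) - 1L) / segments
  radial <- outer(cos(ang), u) + outer(sin(ang), w)
  ring <- sweep(radial * radius, 2L, base, `+`)
  # slanted side normals
  nrm <- radial * len + matrix(axis, segments, 3L, byrow = TRUE) * radius
  nrm <- nrm / sqrt(rowSums(nrm^2))
  pos <- rbind(ring, apex)
  nrm <- rbind(nrm, matrix(axis, 1L))
  s <- segments
  i <- seq_len(s); j <- c(seq_len(s - 1L) + 1L, 1L)
  tri <- cbind(i, j, rep(s + 1L, s))
  new_mesh(pos, nrm, color, tri)
}

perpendicular_unit <- function(axis) {
  ref <- if (abs(axis[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- vcross(axis, ref)
  u / sqrt(sum(u^2))
}

#' Catmull-Rom spline through control points
#'
#' Uniform Catmull-Rom interpolation with endpoint duplication at the
#' termini; the curve passes exactly through every control point and is
#' C1-continuous. The segment midpoint of controls P0..P3 equals
#' `(-P0 + 9 P1 + 9 P2 - P3) / 16`.
#'
#' @param control n x 3 matrix of control points (n >= 2).
#' @param samples_per_segment samples per control-point interval (>= 1).
#' @return `((n - 1) * samples_per_segment + 1) x 3` matrix of curve points.
#' @export
spline_path <- function(control, samples_per_segment = 8L) {
  n <- nrow(control)
  stopifnot(n >= 2L, samples_per_segment >= 1L)
  ext <- rbind(control[1L, ], control, control[n, ])
  s <- samples_per_segment
  out <- matrix(0, (n - 1L) * s + 1L, 3L)
  row <- 1L
  for (seg in seq_len(n - 1L)) {
    p0 <- ext[seg, ]; p1 <- ext[seg + 1L, ]
    p2 <- ext[seg + 2L, ]; p3 <- ext[seg + 3L, ]
    tt <- (seq_len(s) - 1L) / s
    for (t in tt) {
      t2 <- t * t; t3 <- t2 * t
      out[row, ] <- 0.5 * ((2 * p1) + (-p0 + p2) * t +
                           (2 * p0 - 5 * p1 + 4 * p2 - p3) * t2 +
                           (-p0 + 3 * p1 - 3 * p2 + p3) * t3)
      row <- row + 1L
    }
  }
  out[row, ] <- control[n, ]
  out
}

# Parallel-transport frames along a path: returns list(tangent, normal,
# binormal), each n x 3. Avoids the torsion flips of Frenet frames.
transport_frames <- function(path) {
  n <- nrow(path)
  tng <- rbind(path[2L, ] - path[1L, ],
               (path[-(1:2), , drop = FALSE] - path[1:(n - 2L), , drop = FALSE]) / 2,
               path[n, ] - path[n - 1L, ])
  lens <- sqrt(rowSums(tng^2))
  lens[lens < 1e-12] <- 1
  tng <- tng / lens
  nrm <- matrix(0, n, 3L)
  nrm[1L, ] <- perpendicular_unit(tng[1L, ])
  for (i in 2:n) {
    v <- nrm[i - 1L, ]
    t1 <- tng[i, ]
    v <- v - sum(v * t1) * t1    # project previous normal off new tangent
    l <- sqrt(sum(v^2))
    if (l < 1e-9) v <- perpendicular_unit(t1) else v <- v / l
    nrm[i, ] <- v
  }
  bin <- t(vapply(seq_len(n), function(i) vcross(tng[i, ], nrm[i, ]),
                  numeric(3)))
  list(tangent = tng, normal = nrm, binormal = bin)
}

#' Write a mesh as binary little-endian PLY
#' @param mesh a `molmesh`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_ply <- function(mesh, path) {
  n <- nrow(mesh$positions); m <- nrow(mesh$triangles)
  hdr <- paste0(
    "ply\nformat binary_little_endian 1.0\n",
    "element vertex ", n, "\n",
    "property float x\nproperty float y\nproperty float z\n",
    "property float nx\nproperty float ny\nproperty float nz\n",
    "property uchar red\nproperty uchar green\nproperty uchar blue\nproperty uchar alpha\n",
    "element face ", m, "\n",
    "property list uchar int vertex_indices\nend_header\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  for (i in seq_len(n)) {
    writeBin(as.numeric(c(mesh$positions[i, ], mesh$normals[i, ])), con,
             size = 4L, endian = "little")
    writeBin(as.raw(mesh$colors[i, ]), con)
  }
  for (i in seq_len(m)) {
    writeBin(as.raw(3L), con)
    writeBin(as.integer(mesh$triangles[i, ] - 1L), con, size = 4L,
             endian = "little")
  }
  invisible(path)
}

#' Write a mesh as ASCII OBJ
#' @param mesh a `molmesh`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.6f %.6f %.6f", mesh$positions[, 1L],
                     mesh$positions[, 2L], mesh$positions[, 3L]), con)
  writeLines(sprintf("vn %.6f %.6f %.6f", mesh$normals[, 1L],
                     mesh$normals[, 2L], mesh$normals[, 3L]), con)
  writeLines(sprintf("f %d//%d %d//%d %d//%d",
                     mesh$triangles[, 1L], mesh$triangles[, 1L],
                     mesh$triangles[, 2L], mesh$triangles[, 2L],
                     mesh$triangles[, 3L], mesh$triangles[, 3L]), con)
  invisible(path)
}
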