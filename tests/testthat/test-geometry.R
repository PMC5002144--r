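test_that("lod_params follows the documented piecewise table monotonically", {
  expect_equal(lod_params(500),
               list(sphere_subdiv = 3L, cyl_segments = 16L,
                    spline_samples = 16L, surface_spacing = 0.8))
  expect_equal(lod_params(2.4e6),
               list(sphere_subdiv = 0L, cyl_segments = 6L,
                    spline_samples = 2L, surface_spacing = 3.0))
  counts <- round(10^seq(2, 7, by = 0.25))
  prev <- lod_params(counts[[1]])
  for (n in counts[-1]) {
    cur <- lod_params(n)
    expect_lte(cur$sphere_subdiv, prev$sphere_subdiv)
    expect_lte(cur$cyl_segments, prev$cyl_segments)
    expect_lte(cur$spline_samples, prev$spline_samples)
    expect_gte(cur$surface_spacing, prev$surface_spacing)
    prev <- cur
  }
})

test_that("icosphere counts and topology follow the subdivision formulas", {
  for (s in 0:3) {
    m <- sphere_mesh(c(1, 2, 3), 2, s)
    expect_equal(nrow(m$positions), 10 * 4^s + 2)
    expect_equal(nrow(m$triangles), 20 * 4^s)
    expect_valid_mesh(m)
    # closed surface: V - E + F == 2, every edge shared twice
    shares <- edge_share_counts(m)
    expect_equal(names(shares), "2")
    E <- sum(shares) # unique edges
    expect_equal(nrow(m$positions) - E + nrow(m$triangles), 2)
    # radius and radial normals
    r <- unname(sqrt(rowSums(sweep(m$positions, 2, c(1, 2, 3))^2)))
    expect_equal(r, rep(2, length(r)), tolerance = 1e-9)
  }
  expect_error(sphere_mesh(radius = -1), "radius")
})

test_that("cylinder mesh has 2*segments vertices/triangles, radial normals", {
  m <- cylinder_mesh(c(0, 0, 0), c(0, 0, 5), 0.5, 8L)
  expect_equal(nrow(m$positions), 16L)
  expect_equal(nrow(m$triangles), 16L)
  expect_valid_mesh(m)
  expect_true(all(abs(m$normals[, 3]) < 1e-12))  # radial to the z axis
  expect_error(cylinder_mesh(c(0, 0, 0), c(0, 0, 0), 1, 8L), "degenerate")
})

test_that("Catmull-Rom spline interpolates controls and is affine-stable", {
  set.seed(42)
  ctrl <- matrix(rnorm(15), ncol = 3)
  s <- 8L
  path <- spline_path(ctrl, s)
  expect_equal(nrow(path), (nrow(ctrl) - 1L) * s + 1L)
  at_controls <- path[seq(1, nrow(path), by = s), ]
  expect_equal(at_controls, ctrl, tolerance = 1e-12)
  # closed-form midpoint of interior segment
  mid <- spline_path(ctrl, 2L)[4, ]   # midpoint between ctrl 2 and 3
  expect_equal(mid, as.vector((-ctrl[1, ] + 9 * ctrl[2, ] + 9 * ctrl[3, ]
                               - ctrl[4, ]) / 16), tolerance = 1e-12)
  # collinear controls stay collinear
  line <- cbind(0:4, 2 * (0:4), -1 * (0:4))
  lp <- spline_path(line, 5L)
  dir <- c(1, 2, -1) / sqrt(6)
  resid <- lp - as.vector(lp %*% dir) %o% dir
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("VDW, ball-and-stick and stick counts follow their constructions", {
  st <- parse_mol2(c("@<TRIPOS>MOLECULE", "m", "3 2", "SMALL", "NO",
                     "@<TRIPOS>ATOM",
                     " 1 C1 0.0 0.0 0.0 C.3 1 LIG",
                     " 2 C2 1.5 0.0 0.0 C.3 1 LIG",
                     " 3 O1 3.0 0.0 0.0 O.3 1 LIG",
                     "@<TRIPOS>BOND", "1 1 2 1", "2 2 3 1"))
  detail <- list(sphere_subdiv = 1L, cyl_segments = 8L, spline_samples = 4L,
                 surface_spacing = 1)
  v <- build_vdw(st, NULL, detail)
  expect_equal(nrow(v$positions), 3 * 42)
  expect_valid_mesh(v)
  bs <- build_ball_stick(st, NULL, detail)
  expect_equal(nrow(bs$positions), 3 * 42 + 2 * 2 * 16)  # 2 half-cyls per bond
  expect_valid_mesh(bs)
  stick <- build_stick(st, NULL, detail)
  expect_equal(nrow(stick$positions), 2 * 2 * 16 + 3 * 12)  # caps subdiv 0
  expect_valid_mesh(stick)
  # stick with no bonds in selection -> empty mesh plus warning
  lone <- random_carbon_structure(1, seed = 1)
  expect_warning(empty <- build_stick(lone, NULL, detail), "bond")
  expect_equal(nrow(empty$positions), 0L)
})

test_that("CA trace joins consecutive CA atoms within 4.5 Angstrom only", {
  st <- tiny_structure()  # chain A CAs at x = 1.46, 4.5, 8.0
  detail <- list(sphere_subdiv = 1L, cyl_segments = 6L, spline_samples = 4L,
                 surface_spacing = 1)
  m <- build_ca_trace(st, "chain A", detail)
  # CA(res10)-CA(res11): 3.2 A -> drawn; CA(res11)-CA(res12): 3.5 -> drawn
  expect_equal(nrow(m$positions), 2 * 2 * 2 * 6)
  far <- st
  far$coords[[1]][5, ] <- c(16, 1.5, 0)     # break the second link (8 A gap)
  m2 <- build_ca_trace(far, "chain A", detail)
  expect_equal(nrow(m2$positions), 2 * 2 * 6)
})

test_that("tube sweep produces (n-1)*s+1 rings of cyl_segments vertices", {
  st <- make_ideal_helix(10, phi = -70, psi = 150)  # coil-ish extended chain
  st$residues$ss <- "coil"
  for (s in c(4L, 8L)) {
    detail <- list(sphere_subdiv = 1L, cyl_segments = 8L, spline_samples = s,
                   surface_spacing = 1)
    m <- build_tube(st, NULL, detail)
    expect_equal(nrow(m$positions), (9 * s + 1) * 8)
    expect_valid_mesh(m)
  }
  # chains with < 2 trace atoms are skipped with a warning
  one <- make_ideal_helix(2)
  one$atoms <- one$atoms[1:3, ]
  one$coords[[1]] <- one$coords[[1]][1:3, ]
  one <- new_structure(one$atoms, one$coords)
  expect_warning(expect_warning(m3 <- build_tube(one), "skipped"),
                 "no polymer")
  expect_equal(nrow(m3$positions), 0L)
})

test_that("cartoon arrowhead tapers the final sheet residue to a point", {
  st <- make_ideal_helix(6, phi = -120, psi = 130)
  st$residues$ss <- "sheet"
  s <- 8L
  detail <- list(sphere_subdiv = 1L, cyl_segments = 8L, spline_samples = s,
                 surface_spacing = 1)
  m <- build_cartoon(st, NULL, detail)
  expect_valid_mesh(m)
  # ring widths along the last segment decrease monotonically to ~0
  nrings <- 5 * s + 1
  widths <- vapply(seq_len(nrings), function(r) {
    ring <- m$positions[((r - 1) * 8 + 1):(r * 8), ]
    max(dist(ring))
  }, 0)
  last_seg <- widths[(4 * s + 1):nrings]
  expect_true(all(diff(last_seg) < 1e-9))
  expect_lt(last_seg[[length(last_seg)]], 0.3)
  expect_gt(last_seg[[1]], 1.5)   # arrowhead base wider than the strand body
})

test_that("rocket mode draws one cylinder plus one cone per helix run", {
  st <- make_ideal_helix(12)
  st$residues$ss <- "helix"
  detail <- list(sphere_subdiv = 1L, cyl_segments = 10L, spline_samples = 4L,
                 surface_spacing = 1)
  m <- build_rocket(st, NULL, detail)
  # cylinder: 2*seg vertices; cone: seg+1
  expect_equal(nrow(m$positions), 2 * 10 + 10 + 1)
  expect_valid_mesh(m)
})

test_that("coarse surface is closed, spherical for one atom, splits when far", {
  one <- random_carbon_structure(1, seed = 2)
  m <- build_coarse_surface(one, NULL, 0.8)
  expect_valid_mesh(m)
  expect_equal(names(edge_share_counts(m)), "2")   # watertight
  center <- one$coords[[1]][1, ]
  r <- sqrt(rowSums(sweep(m$positions, 2, center)^2))
  expect_lte(max(r) - min(r), 2 * 0.8)
  # two far atoms -> two connected components
  two <- random_carbon_structure(2, seed = 3)
  two$coords[[1]] <- rbind(c(0, 0, 0), c(30, 0, 0))
  m2 <- build_coarse_surface(two, NULL, 0.8)
  comp <- mesh_components(m2)
  expect_equal(comp, 2L)
  # coarser grid gives strictly fewer vertices
  cloud <- random_carbon_structure(60, spread = 10, seed = 4)
  v1 <- nrow(build_coarse_surface(cloud, NULL, 0.8)$positions)
  v2 <- nrow(build_coarse_surface(cloud, NULL, 1.6)$positions)
  expect_lt(v2, v1)
})

test_that("volume contouring recovers analytic isosurfaces and axis order", {
  mp <- make_gaussian_map(rbind(c(2, -1, 3)), sigma = 1.5, spacing = 0.5)
  g <- mp$grid
  # half-max contour of exp(-r^2 / (2 sigma^2)) lies at sigma*sqrt(2 ln 2)
  iso <- contour_volume(g, 0.5)
  expect_valid_mesh(iso)
  r <- sqrt(rowSums(sweep(iso$positions, 2, c(2, -1, 3))^2))
  expect_lt(max(abs(r - 1.5 * sqrt(2 * log(2)))), 0.5)
  # out-of-range level -> warning + empty mesh
  expect_warning(e <- contour_volume(g, max(g$values) * 2), "range")
  expect_equal(nrow(e$positions), 0L)
  # permuting axis order with permuted data gives the same Cartesian mesh
  g2 <- g
  arr <- array(g$values, g$dims)
  g2$values <- as.vector(aperm(arr, c(2, 1, 3)))
  g2$dims <- g$dims[c(2, 1, 3)]
  g2$start <- g$start[c(2, 1, 3)]
  g2$sampling <- g$sampling           # sampling stays in x,y,z order
  g2$axis_order <- c(2L, 1L, 3L)
  iso2 <- contour_volume(g2, 0.5)
  expect_equal(sort(iso$positions[, 1]), sort(iso2$positions[, 1]),
               tolerance = 1e-6)
  expect_equal(nrow(iso$triangles), nrow(iso2$triangles))
})

test_that("merge_meshes concatenates with correct index offsets", {
  a <- sphere_mesh(c(0, 0, 0), 1, 0)
  b <- sphere_mesh(c(5, 0, 0), 1, 0)
  m <- merge_meshes(list(a, b))
  expect_equal(nrow(m$positions), 24L)
  expect_equal(nrow(m$triangles), 40L)
  expect_equal(max(m$triangles), 24L)
  expect_valid_mesh(m)
  empty <- merge_meshes(list())
  expect_equal(nrow(empty$positions), 0L)
  # far beyond 16-bit indices: 6000 subdiv-1 spheres is 252,000 vertices
  s1 <- sphere_mesh(c(0, 0, 0), 1, 1)
  many <- merge_meshes(replicate(6000, s1, simplify = FALSE))
  expect_equal(nrow(many$positions), 252000L)
  expect_equal(max(many$triangles), 252000L)
  expect_gt(nrow(many$positions), 65536)
})

test_that("representation builders are pure: identical inputs, identical meshes", {
  st <- make_ideal_helix(8)
  detail <- lod_params(24)
  cols <- apply_scheme(st, NULL, "ss")
  m1 <- build_cartoon(st, NULL, detail, cols)
  m2 <- build_cartoon(st, NULL, detail, cols)
  expect_identical(m1, m2)
  s1 <- build_coarse_surface(st, NULL, 1.0)
  s2 <- build_coarse_surface(st, NULL, 1.0)
  expect_identical(s1, s2)
})

test_that("PLY and OBJ writers emit readable geometry", {
  td <- withr::local_tempdir()
  m <- sphere_mesh(c(0, 0, 0), 1, 0)
  ply <- file.path(td, "s.ply")
  write_ply(m, ply)
  raw <- readBin(ply, "raw", file.size(ply))
  hdr <- rawToChar(raw[1:200])
  expect_match(hdr, "element vertex 12")
  expect_match(hdr, "binary_little_endian")
  obj <- file.path(td, "s.obj")
  write_obj(m, obj)
  lines <- readLines(obj)
  expect_equal(sum(startsWith(lines, "v ")), 12L)
  expect_equal(sum(startsWith(lines, "f ")), 20L)
})
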