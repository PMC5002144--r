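test_that("auto_fit frames the bounding sphere inside the frustum", {
  set.seed(21)
  st <- random_carbon_structure(40, spread = 12)
  cam <- auto_fit(st, 320, 240, fov_y = 40)
  co <- st$coords[[1]]
  center <- colMeans(co)
  r <- sqrt(max(rowSums(sweep(co, 2, center)^2)))
  d <- sqrt(sum((cam$eye - cam$target)^2))
  expect_equal(cam$target, center)
  expect_equal(d, r / sin(20 * pi / 180) * 1.05, tolerance = 1e-9)
  expect_lt(cam$near, d - r)
  expect_gt(cam$far, d + r)
  # doubling the radius doubles the eye distance
  st2 <- st; st2$coords[[1]] <- sweep(co, 2, center) * 2 +
    matrix(center, nrow(co), 3, byrow = TRUE)
  cam2 <- auto_fit(st2, 320, 240, fov_y = 40)
  expect_equal(sqrt(sum((cam2$eye - cam2$target)^2)), 2 * d, tolerance = 1e-9)
  expect_error(auto_fit(matrix(0, 0, 3)), "empty")
})

test_that("a single atom projects to the image centre pixel", {
  atoms <- random_carbon_structure(1, seed = 9)
  mesh <- sphere_mesh(atoms$coords[[1]][1, ], 0.5, 1)
  cam <- auto_fit(mesh, 101, 101)
  img <- rasterize(new_scene(mesh), cam)
  covered <- which(img$depth < Inf, arr.ind = TRUE)
  expect_equal(round(mean(covered[, 1])), 51)   # centre row
  expect_equal(round(mean(covered[, 2])), 51)   # centre column
  # all mesh vertices project inside the frustum after fit
  view <- molviewr:::camera_view(cam)
  pe <- t(view$R %*% t(mesh$positions) + as.vector(view$t))
  tanf <- tan(cam$fov_y / 2 * pi / 180)
  expect_true(all(pe[, 3] > cam$near & pe[, 3] < cam$far))
  expect_true(all(abs(pe[, 1] / pe[, 3]) <= tanf * 101 / 101 + 1e-9))
  expect_true(all(abs(pe[, 2] / pe[, 3]) <= tanf + 1e-9))
})

test_that("phong_shade matches its closed form in canonical configurations", {
  mat <- new_material(0.2, 0.7, 0.3, 16)
  N <- c(0, 0, 1)
  # aligned: N == L == V
  got <- phong_shade(N, N, N, c(200, 100, 50), mat)
  expect_equal(got,
               as.integer(pmin(round(c(200, 100, 50) * 0.9 + 255 * 0.3), 255)))
  # grazing: N.L == 0 and R.V <= 0 -> ambient only
  got2 <- phong_shade(N, c(0, 0, 1), c(1, 0, 0), c(200, 100, 50), mat)
  expect_equal(got2, as.integer(round(c(200, 100, 50) * 0.2)))
  # 45 degrees, V == L
  L <- c(0, 0, 1)
  N45 <- c(sin(pi / 4), 0, cos(pi / 4))
  nl <- cos(pi / 4)
  r <- 2 * nl * N45 - L
  rv <- max(sum(r * L), 0)
  expected <- as.integer(pmin(pmax(round(
    200 * (0.2 + 0.7 * nl) + 255 * 0.3 * rv^16), 0), 255))
  expect_equal(phong_shade(N45, L, L, c(200, 0, 0), mat)[1], expected)
})

test_that("phong_shade is monotone in N.L for fixed other inputs", {
  mat <- new_material()
  L <- c(0, 0, 1); V <- c(0, 0, 1)
  angles <- seq(0, pi / 2, length.out = 20)
  vals <- vapply(angles, function(a) {
    N <- c(sin(a), 0, cos(a))
    phong_shade(N, V, L, c(180, 180, 180), mat)[1]
  }, 0L)
  expect_true(all(diff(vals) <= 0))  # N.L decreases along the sweep
})

test_that("rasterizer coverage equals the brute-force pixel-centre oracle", {
  # one axis-aligned triangle at fixed depth, camera built by hand
  cam <- new_camera(eye = c(0, 0, -10), target = c(0, 0, 0), fov_y = 60,
                    near = 1, far = 100, width = 64L, height = 64L)
  tri <- rbind(c(-3, -2, 0), c(4, -1, 0), c(0, 5, 0))
  mesh <- new_mesh(tri, matrix(rep(c(0, 0, -1), 3), 3, byrow = TRUE),
                   c(255L, 0L, 0L, 255L), matrix(1:3, 1))
  img <- rasterize(new_scene(mesh), cam)
  covered <- img$depth < Inf
  # oracle: project vertices, point-in-triangle at pixel centres
  view <- molviewr:::camera_view(cam)
  pe <- t(view$R %*% t(tri) + as.vector(view$t))
  tanf <- tan(cam$fov_y / 2 * pi / 180)
  sx <- (pe[, 1] / (pe[, 3] * tanf) + 1) * 32
  sy <- (1 - pe[, 2] / (pe[, 3] * tanf)) * 32
  oracle <- matrix(FALSE, 64, 64)
  for (px in 1:64) for (py in 1:64) {
    x <- px - 0.5; y <- py - 0.5
    d <- function(i, j) (sx[j] - sx[i]) * (y - sy[i]) - (sy[j] - sy[i]) * (x - sx[i])
    s1 <- d(1, 2); s2 <- d(2, 3); s3 <- d(3, 1)
    oracle[py, px] <- (s1 >= 0 & s2 >= 0 & s3 >= 0) |
                      (s1 <= 0 & s2 <= 0 & s3 <= 0)
  }
  expect_equal(unname(covered), oracle)
})

test_that("z-buffer: the nearer triangle wins every overlapping pixel", {
  cam <- new_camera(eye = c(0, 0, -10), target = c(0, 0, 0), fov_y = 60,
                    near = 1, far = 200, width = 48L, height = 48L)
  big <- function(z, col) new_mesh(
    rbind(c(-6, -6, z), c(6, -6, z), c(0, 8, z)),
    matrix(rep(c(0, 0, -1), 3), 3, byrow = TRUE), col, matrix(1:3, 1))
  near <- big(0, c(255L, 0L, 0L, 255L))    # depth 10 from the eye
  far <- big(5, c(0L, 255L, 0L, 255L))     # depth 15
  img <- rasterize(new_scene(list(far, near)), cam)
  covered_far <- rasterize(new_scene(far), cam)$depth < Inf
  covered_near <- rasterize(new_scene(near), cam)$depth < Inf
  overlap <- covered_far & covered_near
  # wherever both cover, the red (near) triangle is visible
  reds <- img$rgba[, , 1][overlap]
  greens <- img$rgba[, , 2][overlap]
  expect_true(all(reds > greens))
})

test_that("depth-test winners have the smaller interpolated depth (property)", {
  set.seed(77)
  cam <- new_camera(eye = c(0, 0, -10), target = c(0, 0, 0), fov_y = 60,
                    near = 0.5, far = 500, width = 32L, height = 32L)
  for (rep in 1:60) {
    t1 <- matrix(runif(9, -4, 4), 3); t1[, 3] <- runif(1, 0, 20)
    t2 <- matrix(runif(9, -4, 4), 3); t2[, 3] <- runif(1, 0, 20)
    mk <- function(tr, col) new_mesh(tr, matrix(rep(c(0, 0, -1), 3), 3,
                                                byrow = TRUE), col,
                                     matrix(1:3, 1))
    m1 <- mk(t1, c(255L, 0L, 0L, 255L)); m2 <- mk(t2, c(0L, 255L, 0L, 255L))
    d1 <- rasterize(new_scene(m1), cam)$depth
    d2 <- rasterize(new_scene(m2), cam)$depth
    both <- rasterize(new_scene(list(m1, m2)), cam)$depth
    expect_equal(both, pmin(d1, d2), tolerance = 1e-9)
  }
})

test_that("PNG round trip is bit-exact and renders are byte-identical", {
  td <- withr::local_tempdir()
  st <- make_ideal_helix(8)
  mesh <- build_cartoon(st, NULL, lod_params(24),
                        apply_scheme(st, NULL, "ss"))
  cam <- auto_fit(mesh, 120, 90)
  img <- rasterize(new_scene(mesh), cam)
  p1 <- file.path(td, "a.png"); p2 <- file.path(td, "b.png")
  write_png(img, p1)
  back <- read_png(p1)
  expect_identical(as.integer(back), as.integer(img$rgba))
  expect_equal(dim(back), c(90L, 120L, 4L))
  img2 <- rasterize(new_scene(mesh), cam)
  write_png(img2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  # empty scene: all background
  empty <- rasterize(new_scene(list()), cam)
  expect_true(all(empty$rgba[, , 1] == 255L))
  expect_true(all(empty$depth == Inf))
})

test_that("render_frames writes one deterministic PNG per frame", {
  td <- withr::local_tempdir()
  st <- make_ideal_helix(6)
  base <- st$coords[[1]]
  frames <- lapply(1:3, function(k)
    list(time = k - 1, box = matrix(0, 3, 3),
         coords = base + cbind(rep(5 * (k - 1), nrow(base)), 0, 0)))
  traj <- new_trajectory(n_atoms(st), frames)
  paths <- render_frames(st, traj, file.path(td, "frames"),
                         repr = "tube", width = 80L, height = 60L)
  expect_length(paths, 3L)
  expect_true(all(file.exists(paths)))
  expect_equal(basename(paths[1]), "frame_000001.png")
  # camera is fixed on frame 1, so translating +x moves the rendered centroid
  colmass <- vapply(paths, function(p) {
    a <- read_png(p)
    cov <- a[, , 1] < 250 | a[, , 2] < 250 | a[, , 3] < 250
    if (!any(cov)) return(NA_real_)
    mean(which(cov, arr.ind = TRUE)[, 2])
  }, 0)
  dc <- diff(as.numeric(stats::na.omit(colmass)))
  expect_true(all(dc > 0) || all(dc < 0))   # strictly monotone shift
  # identical frames give identical bytes
  traj2 <- new_trajectory(n_atoms(st), frames[c(1, 1)])
  paths2 <- render_frames(st, traj2, file.path(td, "same"), repr = "tube",
                          width = 80L, height = 60L)
  expect_identical(readBin(paths2[1], "raw", file.size(paths2[1])),
                   readBin(paths2[2], "raw", file.size(paths2[2])))
  # atom-count mismatch rejected before writing anything
  badtraj <- new_trajectory(3L, list(list(time = 0, box = matrix(0, 3, 3),
                                          coords = matrix(0, 3, 3))))
  expect_error(render_frames(st, badtraj, file.path(td, "no")), "atoms")
  expect_false(dir.exists(file.path(td, "no")) &&
               length(list.files(file.path(td, "no"))) > 0)
})
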