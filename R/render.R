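#' @title Software renderer
#' @description
#' Perspective camera, z-buffered triangle rasterizer with perspective-
#' correct attribute interpolation and per-pixel Phong shading, PNG export,
#' and trajectory frame-sequence rendering. Rendering is deterministic:
#' a fixed scene and camera produce byte-identical PNGs (shading is rounded
#' half-to-even before quantization, and no antialiasing is applied by
#' default).
#' @name renderer
NULL

#' Construct a camera
#' @param eye,target 3-vectors (Angstrom), must differ.
#' @param up unit up vector.
#' @param fov_y vertical field of view, degrees, in (0, 180).
#' @param near,far clip distances, `0 < near < far`.
#' @param width,height image size in pixels.
#' @return an object of class `molcamera`.
#' @export
new_camera <- function(eye, target, up = c(0, 1, 0), fov_y = 40,
                       near = 0.1, far = 1000, width = 640L, height = 480L) {
  if (near <= 0 || far <= near) stop("camera requires 0 < near < far")
  if (fov_y <= 0 || fov_y >= 180) stop("fov_y must be in (0, 180)")
  if (sqrt(sum((eye - target)^2)) < 1e-9) stop("eye must differ from target")
  up <- up / sqrt(sum(up^2))
  structure(list(eye = eye, target = target, up = up, fov_y = fov_y,
                 near = near, far = far, width = as.integer(width),
                 height = as.integer(height)),
            class = "molcamera")
}

#' Fit a camera to bounds
#'
#' Places the eye on the -z axis through the centroid at distance
#' `r / sin(fov_y / 2) * 1.05`, with `near = distance - 1.1 r` (clamped
#' positive) and `far = distance + 1.1 r`, so the whole bounding sphere is
#' inside the frustum.
#'
#' @param x a `molstruct`, `molmesh`, or an `n x 3` coordinate matrix.
#' @param width,height image size in pixels.
#' @param fov_y vertical field of view (degrees).
#' @return a `molcamera`.
#' @export
auto_fit <- function(x, width = 640L, height = 480L, fov_y = 40) {
  pts <- if (inherits(x, "molstruct")) x$coords[[1L]]
         else if (inherits(x, "molmesh")) x$positions
         else as.matrix(x)
  if (!nrow(pts)) stop("empty bounds: nothing to fit")
  center <- colMeans(pts)
  r <- sqrt(max(rowSums(sweep(pts, 2L, center)^2)))
  r_eff <- max(r, 1)
  dist <- r_eff / sin(fov_y / 2 * pi / 180) * 1.05
  near <- max(dist - r_eff * 1.1, dist * 1e-3)
  new_camera(eye = center - c(0, 0, dist), target = center, up = c(0, 1, 0),
             fov_y = fov_y, near = near, far = dist + r_eff * 1.1,
             width = width, height = height)
}

#' Default material
#' @param k_ambient,k_diffuse,k_specular Phong coefficients in `[0, 1]`.
#' @param shininess specular exponent (>= 1).
#' @return a material list.
#' @export
new_material <- function(k_ambient = 0.25, k_diffuse = 0.65,
                         k_specular = 0.35, shininess = 32) {
  stopifnot(k_ambient >= 0, k_ambient <= 1, k_diffuse >= 0, k_diffuse <= 1,
            k_specular >= 0, k_specular <= 1, shininess >= 1)
  list(k_ambient = k_ambient, k_diffuse = k_diffuse,
       k_specular = k_specular, shininess = shininess)
}

#' Construct a scene
#' @param meshes a `molmesh` or list of them.
#' @param material Phong material ([new_material()]).
#' @param light_dir directional light in camera space (unit; the default is
#'   a headlight along the view axis).
#' @param background RGBA background colour.
#' @return a scene list.
#' @export
new_scene <- function(meshes, material = new_material(),
                      light_dir = c(0, 0, 1),
                      background = c(255L, 255L, 255L, 255L)) {
  if (inherits(meshes, "molmesh")) meshes <- list(meshes)
  light_dir <- light_dir / sqrt(sum(light_dir^2))
  list(meshes = meshes, material = material, light_dir = light_dir,
       background = as.integer(background))
}

#' Phong shading of one fragment
#'
#' Per channel: `c * (k_a + k_d * max(N.L, 0)) +
#' 255 * k_s * max(R.V, 0)^shininess`, with `R` the reflection of `-L`
#' about `N`, clamped to `[0, 255]`. Monotonically non-decreasing in `N.L`.
#'
#' @param normal,view_dir,light_dir unit 3-vectors.
#' @param base_color RGB(A) vector, 0-255.
#' @param material a [new_material()] list.
#' @return shaded RGB integer vector (alpha unchanged by shading).
#' @export
phong_shade <- function(normal, view_dir, light_dir, base_color,
                        material = new_material()) {
  nl <- max(sum(normal * light_dir), 0)
  r <- 2 * sum(normal * light_dir) * normal - light_dir
  rv <- max(sum(r * view_dir), 0)
  spec <- 255 * material$k_specular * rv^material$shininess
  ch <- base_color[1:3] * (material$k_ambient + material$k_diffuse * nl) + spec
  as.integer(pmin(pmax(round(ch), 0), 255))
}

# look-at view matrix (4x4) mapping world -> camera space (-z is forward in
# GL convention; here we use +z forward so depth == camera-space z > 0)
camera_view <- function(camera) {
  f <- camera$target - camera$eye
  f <- f / sqrt(sum(f^2))
  r <- vcross(f, camera$up)
  if (sqrt(sum(r^2)) < 1e-9) {
    alt <- if (abs(f[2L]) < 0.9) c(0, 1, 0) else c(1, 0, 0)
    r <- vcross(f, alt)
  }
  r <- r / sqrt(sum(r^2))
  u <- vcross(r, f)
  R <- rbind(r, u, f)
  list(R = R, t = -R %*% camera$eye)
}

#' Rasterize a scene
#'
#' Perspective projection, no back-face culling, z-buffer at pixel centres,
#' perspective-correct interpolation of normals and colours, per-pixel
#' Phong shading. Alpha below 255 is rendered opaque (with a warning).
#'
#' @param scene a [new_scene()] list.
#' @param camera a `molcamera`.
#' @return an object of class `molimage`: list with `width`, `height`,
#'   `rgba` (height x width x 4 integer array, row 1 = top) and `depth`
#'   (height x width matrix of camera-space depths, `Inf` = background).
#' @export
rasterize <- function(scene, camera) {
  if (!inherits(camera, "molcamera")) stop("camera must be a molcamera")
  W <- camera$width; H <- camera$height
  rgba <- array(rep(scene$background, each = H * W), c(H, W, 4L))
  depth <- matrix(Inf, H, W)
  view <- camera_view(camera)
  tanf <- tan(camera$fov_y / 2 * pi / 180)
  aspect <- W / H
  mat <- scene$material
  L <- scene$light_dir
  warned_alpha <- FALSE
  for (mesh in scene$meshes) {
    if (!nrow(mesh$triangles)) next
    if (!warned_alpha && any(mesh$colors[, 4L] < 255L)) {
      warning("alpha < 255 rendered opaque")
      warned_alpha <- TRUE
    }
    pe <- t(view$R %*% t(mesh$positions) + as.vector(view$t))  # camera space
    ne <- t(view$R %*% t(mesh$normals))
    z <- pe[, 3L]
    # screen coordinates of vertices (pixel units; y down)
    sx <- (pe[, 1L] / (z * tanf * aspect) + 1) * 0.5 * W
    sy <- (1 - pe[, 2L] / (z * tanf)) * 0.5 * H
    tris <- mesh$triangles
    for (t in seq_len(nrow(tris))) {
      v <- tris[t, ]
      zv <- z[v]
      if (any(zv < camera$near) || all(zv > camera$far)) next
      x0 <- sx[v]; y0 <- sy[v]
      xmin <- max(1L, as.integer(floor(min(x0) - 0.5)) + 1L)
      xmax <- min(W, as.integer(ceiling(max(x0) + 0.5)))
      ymin <- max(1L, as.integer(floor(min(y0) - 0.5)) + 1L)
      ymax <- min(H, as.integer(ceiling(max(y0) + 0.5)))
      if (xmin > xmax || ymin > ymax) next
      area <- (x0[2L] - x0[1L]) * (y0[3L] - y0[1L]) -
              (x0[3L] - x0[1L]) * (y0[2L] - y0[1L])
      if (abs(area) < 1e-12) next
      px <- seq(xmin, xmax) - 0.5
      py <- seq(ymin, ymax) - 0.5
      nx <- length(px); ny <- length(py)
      PX <- rep(px, times = ny); PY <- rep(py, each = nx)
      w0 <- ((x0[2L] - PX) * (y0[3L] - PY) - (x0[3L] - PX) * (y0[2L] - PY)) / area
      w1 <- ((x0[3L] - PX) * (y0[1L] - PY) - (x0[1L] - PX) * (y0[3L] - PY)) / area
      w2 <- 1 - w0 - w1
      inside <- w0 >= 0 & w1 >= 0 & w2 >= 0
      if (!any(inside)) next
      w0 <- w0[inside]; w1 <- w1[inside]; w2 <- w2[inside]
      ix <- PX[inside] + 0.5; iy <- PY[inside] + 0.5
      # perspective-correct: interpolate 1/z and attribute/z
      iz <- w0 / zv[1L] + w1 / zv[2L] + w2 / zv[3L]
      zf <- 1 / iz
      cols <- as.integer(ix)
      rows <- as.integer(iy)
      lin <- rows + (cols - 1L) * H
      closer <- zf < depth[lin]
      if (!any(closer)) next
      keep <- which(closer)
      w0 <- w0[keep]; w1 <- w1[keep]; w2 <- w2[keep]
      zf <- zf[keep]; lin <- lin[keep]
      pa <- function(attr) {
        (w0 * attr[v[1L]] / zv[1L] + w1 * attr[v[2L]] / zv[2L] +
         w2 * attr[v[3L]] / zv[3L]) * zf
      }
      fx <- pa(pe[, 1L]); fy <- pa(pe[, 2L]); fz <- zf
      nxv <- pa(ne[, 1L]); nyv <- pa(ne[, 2L]); nzv <- pa(ne[, 3L])
      nlen <- sqrt(nxv^2 + nyv^2 + nzv^2); nlen[nlen < 1e-12] <- 1
      nxv <- nxv / nlen; nyv <- nyv / nlen; nzv <- nzv / nlen
      cr <- pa(mesh$colors[, 1L]); cg <- pa(mesh$colors[, 2L])
      cb <- pa(mesh$colors[, 3L])
      vlen <- sqrt(fx^2 + fy^2 + fz^2); vlen[vlen < 1e-12] <- 1
      vx <- -fx / vlen; vy <- -fy / vlen; vz <- -fz / vlen
      # two-sided shading: flip normals facing away from the viewer
      ndv <- nxv * vx + nyv * vy + nzv * vz
      flip <- ndv < 0
      nxv[flip] <- -nxv[flip]; nyv[flip] <- -nyv[flip]; nzv[flip] <- -nzv[flip]
      nl <- pmax(nxv * L[1L] + nyv * L[2L] + nzv * L[3L], 0)
      tw <- 2 * (nxv * L[1L] + nyv * L[2L] + nzv * L[3L])
      rx <- tw * nxv - L[1L]; ry <- tw * nyv - L[2L]; rz <- tw * nzv - L[3L]
      rv <- pmax(rx * vx + ry * vy + rz * vz, 0)
      spec <- 255 * mat$k_specular * rv^mat$shininess
      fac <- mat$k_ambient + mat$k_diffuse * nl
      depth[lin] <- zf
      rgba[lin] <- pmin(pmax(round(cr * fac + spec), 0), 255)
      rgba[lin + H * W] <- pmin(pmax(round(cg * fac + spec), 0), 255)
      rgba[lin + 2L * H * W] <- pmin(pmax(round(cb * fac + spec), 0), 255)
      rgba[lin + 3L * H * W] <- 255L
    }
  }
  structure(list(width = W, height = H, rgba = rgba, depth = depth),
            class = "molimage")
}

#' @export
print.molimage <- function(x, ...) {
  bg <- x$depth == Inf
  cat(sprintf("<molimage> %d x %d, %.1f%% covered\n", x$width, x$height,
              100 * mean(!bg)))
  invisible(x)
}

#' Write an image buffer as PNG
#'
#' 8-bit RGBA; decoding the file reproduces the buffer bit-exactly, and two
#' renders of the same scene produce byte-identical files.
#'
#' @param image a `molimage` (or height x width x 4 array, 0-255).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_png <- function(image, path) {
  arr <- if (inherits(image, "molimage")) image$rgba else image
  png::writePNG(arr / 255, path)
  invisible(path)
}

#' Read a PNG into a 0-255 integer array
#' @param path PNG file.
#' @return height x width x channels integer array.
#' @export
read_png <- function(path) {
  a <- png::readPNG(path)
  storage.mode(a) <- "double"
  array(as.integer(round(a * 255)), dim(a))
}

#' Render a trajectory as a numbered PNG frame sequence
#'
#' For each frame the structure's coordinates are substituted, the geometry
#' rebuilt, the scene rendered with a camera fitted once on the first
#' frame, and `frame_%06d.png` written to `outdir`.
#'
#' @param structure a `molstruct` whose atom count matches the trajectory.
#' @param trajectory a `moltraj`.
#' @param outdir output directory (created if missing).
#' @param repr representation builder name (`"cartoon"`, `"tube"`,
#'   `"vdw"`, `"ball_stick"`, `"stick"`, `"ca_trace"`, `"rocket"`,
#'   `"surface"`).
#' @param scheme colour scheme for [apply_scheme()].
#' @param width,height image size.
#' @param detail optional [lod_params()] override.
#' @return character vector of written file paths.
#' @export
render_frames <- function(structure, trajectory, outdir,
                          repr = "cartoon", scheme = "chain",
                          width = 320L, height = 240L, detail = NULL) {
  if (trajectory$n_atoms != n_atoms(structure))
    stop(sprintf("trajectory has %d atoms but structure has %d",
                 trajectory$n_atoms, n_atoms(structure)))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(detail)) detail <- lod_params(n_atoms(structure))
  camera <- NULL
  paths <- character(0)
  for (k in seq_along(trajectory$frames)) {
    st <- structure
    st$coords[[1L]] <- trajectory$frames[[k]]$coords
    cols <- apply_scheme(st, NULL, scheme)
    mesh <- build_representation(st, repr, NULL, detail, cols)
    if (is.null(camera)) camera <- auto_fit(mesh, width, height)
    img <- rasterize(new_scene(mesh), camera)
    p <- file.path(outdir, sprintf("frame_%06d.png", k))
    write_png(img, p)
    paths[[k]] <- p
  }
  paths
}

#' Dispatch a representation builder by name
#' @param structure a `molstruct`.
#' @param repr builder name (see [render_frames()]).
#' @param selection,detail,colors,model passed through.
#' @return a `molmesh`.
#' @export
build_representation <- function(structure, repr, selection = NULL,
                                 detail = lod_params(n_atoms(structure)),
                                 colors = NULL, model = 1L) {
  repr <- match.arg(repr, c("cartoon", "tube", "vdw", "ball_stick", "stick",
                            "ca_trace", "rocket", "surface"))
  fn <- switch(repr,
    cartoon = build_cartoon, tube = build_tube, vdw = build_vdw,
    ball_stick = build_ball_stick, stick = build_stick,
    ca_trace = build_ca_trace, rocket = build_rocket,
    surface = function(structure, selection, detail, colors, model)
      build_coarse_surface(structure, selection, detail,
                           color = if (is.null(colors)) GREY else colors,
                           model = model))
  fn(structure, selection, detail, colors, model)
}
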