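#' @title Volume grids and trajectories
#' @description
#' `volgrid`: an axis-ordered 3-D scalar grid with unit-cell geometry, as
#' stored in CCP4 map files. `moltraj`: per-frame coordinate sets (plus box
#' and time) decoded from TRR/XTC files or multi-model structures. All
#' in-memory lengths are Angstrom; GRO/TRR/XTC apply the nm-to-Angstrom
#' factor of 10 exactly once, on read.
#' @name volume-trajectory
NULL

# --- raw-vector cursor helpers (XDR is big-endian) -------------------------
new_cursor <- function(raw) {
  e <- new.env(parent = emptyenv()); e$raw <- raw; e$pos <- 0L; e
}
cur_left <- function(e) length(e$raw) - e$pos
cur_take <- function(e, n) {
  if (cur_left(e) < n) stop("unexpected end of file")
  out <- e$raw[(e$pos + 1L):(e$pos + n)]
  e$pos <- e$pos + n
  out
}
cur_int <- function(e, n = 1L, endian = "big")
  readBin(cur_take(e, 4L * n), "integer", n, size = 4L, endian = endian)
cur_float <- function(e, n = 1L, endian = "big")
  readBin(cur_take(e, 4L * n), "double", n, size = 4L, endian = endian)
cur_double <- function(e, n = 1L, endian = "big")
  readBin(cur_take(e, 8L * n), "double", n, size = 8L, endian = endian)

wr_int <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "big")
wr_float <- function(x) writeBin(as.numeric(x), raw(), size = 4L, endian = "big")

read_file_raw <- function(path) readBin(path, "raw", file.size(path))

#' Construct a trajectory
#' @param n_atoms atoms per frame.
#' @param frames list of frames, each `list(time, box, coords)` with `coords`
#'   an `n_atoms x 3` matrix (Angstrom), `box` a 3x3 matrix (Angstrom) and
#'   `time` in ps.
#' @return an object of class `moltraj`.
#' @export
new_trajectory <- function(n_atoms, frames) {
  for (f in frames) {
    if (!is.matrix(f$coords) || nrow(f$coords) != n_atoms ||
        ncol(f$coords) != 3L)
      stop("every frame must have exactly n_atoms x 3 coordinates")
  }
  times <- vapply(frames, function(f) f$time, 0.0)
  if (is.unsorted(times)) stop("frames must be time-ordered")
  structure(list(n_atoms = as.integer(n_atoms), frames = frames),
            class = "moltraj")
}

#' @export
print.moltraj <- function(x, ...) {
  times <- vapply(x$frames, function(f) f$time, 0.0)
  cat(sprintf("<moltraj> %d frames x %d atoms, t = %g..%g ps\n",
              length(x$frames), x$n_atoms,
              if (length(times)) min(times) else NA,
              if (length(times)) max(times) else NA))
  invisible(x)
}

#' Convert a multi-model structure to a trajectory
#'
#' One frame per model; time is the model index (1-based), box is zero.
#' Frame coordinates are the model coordinates, bit-exactly.
#'
#' @param structure a `molstruct` with one or more models.
#' @return a `moltraj`.
#' @export
structure_to_trajectory <- function(structure) {
  frames <- lapply(seq_along(structure$coords), function(k)
    list(time = as.numeric(k), box = matrix(0, 3L, 3L),
         coords = structure$coords[[k]]))
  new_trajectory(n_atoms(structure), frames)
}

# --- CCP4 ------------------------------------------------------------------

#' Read a CCP4 density map
#'
#' Parses the 1024-byte header (column/row/section counts, mode, start
#' indices, sampling, cell, axis order, statistics), detects byte order from
#' the MACHST stamp (falling back to mode plausibility), skips the symmetry
#' block, and reads the data: mode 2 (float32), mode 1 (int16) and mode 0
#' (signed byte) are supported, all mapped to doubles.
#'
#' @param path file path, or `bytes` a raw vector.
#' @param bytes raw vector alternative to `path`.
#' @return an object of class `volgrid` with fields `dims` (counts along the
#'   fastest to slowest file axes), `axis_order` (which of x,y,z each file
#'   axis is), `start`, `sampling`, `cell`, `values` (array in file order)
#'   and `stats`.
#' @export
read_ccp4 <- function(path = NULL, bytes = NULL) {
  if (is.null(bytes)) bytes <- read_file_raw(path)
  if (length(bytes) < 1024L) stop("not a CCP4 map: shorter than its header")
  machst <- bytes[213L:216L]  # word 54
  endian <- if (machst[1L] == as.raw(0x44)) "little"
            else if (machst[1L] == as.raw(0x11)) "big"
            else NA
  hdr_words <- function(end) readBin(bytes[1:1024], "integer", 256L,
                                     size = 4L, endian = end)
  if (is.na(endian)) {
    for (cand in c("little", "big")) {
      h <- hdr_words(cand)
      if (h[4L] >= 0L && h[4L] <= 6L && all(h[1:3] > 0L) && all(h[1:3] < 1e6)) {
        endian <- cand; break
      }
    }
    if (is.na(endian)) stop("cannot determine CCP4 byte order")
  }
  h <- hdr_words(endian)
  hf <- readBin(bytes[1:1024], "double", 256L, size = 4L, endian = endian)
  dims <- h[1:3]
  mode <- h[4L]
  start <- h[5:7]
  sampling <- h[8:10]
  cell <- hf[11:16]
  axis <- h[17:19]
  stats <- c(min = hf[20L], max = hf[21L], mean = hf[22L])
  nsymbt <- h[24L]
  if (any(dims <= 0L)) stop("CCP4 header: non-positive dimensions")
  if (any(cell[1:3] <= 0) || any(cell[4:6] <= 0) || any(cell[4:6] >= 180))
    stop("CCP4 header: invalid cell")
  if (!setequal(axis, 1:3)) stop("CCP4 header: MAPC/MAPR/MAPS not a permutation")
  n <- prod(dims)
  off <- 1024L + nsymbt
  avail <- length(bytes) - off
  vals <- switch(as.character(mode),
    "2" = {
      if (avail < 4L * n) stop(sprintf(
        "CCP4 map truncated: %d values expected, %d bytes available", n, avail))
      readBin(bytes[(off + 1L):(off + 4L * n)], "double", n, size = 4L,
              endian = endian)
    },
    "1" = {
      if (avail < 2L * n) stop("CCP4 map truncated")
      as.numeric(readBin(bytes[(off + 1L):(off + 2L * n)], "integer", n,
                         size = 2L, signed = TRUE, endian = endian))
    },
    "0" = {
      if (avail < n) stop("CCP4 map truncated")
      as.numeric(readBin(bytes[(off + 1L):(off + n)], "integer", n,
                         size = 1L, signed = TRUE))
    },
    stop(sprintf("unsupported CCP4 mode %d (modes 0, 1, 2 are supported)",
                 mode)))
  structure(list(dims = dims, axis_order = axis, start = start,
                 sampling = sampling, cell = cell, values = vals,
                 stats = stats, mode = mode),
            class = "volgrid")
}

#' @export
print.volgrid <- function(x, ...) {
  cat(sprintf(
    "<volgrid> %d x %d x %d (axes %s), cell %.2f %.2f %.2f A, mean %.4g\n",
    x$dims[1L], x$dims[2L], x$dims[3L],
    paste(c("x", "y", "z")[x$axis_order], collapse = ""),
    x$cell[1L], x$cell[2L], x$cell[3L], x$stats[["mean"]]))
  invisible(x)
}

#' Write a CCP4 density map (mode 2, little-endian)
#'
#' @param grid a `volgrid`.
#' @param path optional output file.
#' @return raw vector of the map bytes (invisibly when `path` given).
#' @export
write_ccp4 <- function(grid, path = NULL) {
  n <- prod(grid$dims)
  stopifnot(length(grid$values) == n)
  w <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), raw(), size = 4L, endian = "little")
  hdr <- c(w(grid$dims), w(2L), w(grid$start), w(grid$sampling),
           wf(grid$cell), w(grid$axis_order),
           wf(c(min(grid$values), max(grid$values), mean(grid$values))),
           w(0L),   # ISPG
           w(0L))   # NSYMBT
  hdr <- c(hdr, raw(4L * (52L - 25L + 1L - 1L)))  # words 26..52 zero
  hdr <- c(hdr, charToRaw("MAP "))                # word 53
  hdr <- c(hdr, as.raw(c(0x44, 0x41, 0x00, 0x00)))  # word 54 MACHST little
  hdr <- c(hdr, wf(stats::sd(grid$values)))       # word 55 RMS
  hdr <- c(hdr, raw(1024L - length(hdr)))
  stopifnot(length(hdr) == 1024L)
  out <- c(hdr, writeBin(as.numeric(grid$values), raw(), size = 4L,
                         endian = "little"))
  if (!is.null(path)) {
    writeBin(out, path)
    return(invisible(out))
  }
  out
}

# --- TRR -------------------------------------------------------------------

TRR_MAGIC <- 1993L
TRR_VERSION <- "GMX_trn_file"

#' Read a Gromacs TRR trajectory
#'
#' XDR big-endian frames: magic 1993, version string, per-block byte sizes
#' (box, positions, velocities, forces), atom count, step, time. Positions
#' and box are converted nm to Angstrom; velocity and force blocks are
#' skipped. Single and double precision are auto-detected from block sizes.
#'
#' @param path file path, or `bytes` a raw vector.
#' @param bytes raw vector alternative to `path`.
#' @return a `moltraj`.
#' @export
read_trr <- function(path = NULL, bytes = NULL) {
  if (is.null(bytes)) bytes <- read_file_raw(path)
  cur <- new_cursor(bytes)
  frames <- list()
  natoms0 <- NULL
  while (cur_left(cur) >= 4L) {
    frame <- tryCatch(trr_read_frame(cur), error = function(err) {
      if (length(frames))
        stop(sprintf("truncated TRR frame after %d complete frame(s): %s",
                     length(frames), conditionMessage(err)))
      stop(conditionMessage(err))
    })
    if (is.null(natoms0)) natoms0 <- nrow(frame$coords)
    frames[[length(frames) + 1L]] <- frame
  }
  if (!length(frames)) stop("empty TRR file")
  new_trajectory(natoms0, frames)
}

trr_read_frame <- function(cur) {
  magic <- cur_int(cur)
  if (magic != TRR_MAGIC)
    stop(sprintf("not a TRR frame: magic %d != 1993", magic))
  slen <- cur_int(cur)
  vlen <- cur_int(cur)
  cur_take(cur, 4L * ((vlen + 3L) %/% 4L))  # version string, padded
  if (slen != vlen + 1L) stop("malformed TRR version string")
  sz <- cur_int(cur, 10L)  # ir, e, box, vir, pres, top, sym, x, v, f
  natoms <- cur_int(cur)
  step <- cur_int(cur)
  nre <- cur_int(cur)
  box_size <- sz[3L]; x_size <- sz[8L]; v_size <- sz[9L]; f_size <- sz[10L]
  real_size <- if (box_size > 0L) box_size %/% 9L
               else if (x_size > 0L) x_size %/% (3L * natoms)
               else 4L
  if (!real_size %in% c(4L, 8L)) stop("TRR real size is neither 4 nor 8")
  rd <- function(n) if (real_size == 4L) cur_float(cur, n) else cur_double(cur, n)
  time <- rd(1L)
  lambda <- rd(1L)
  cur_take(cur, sz[1L] + sz[2L])  # ir/e blocks (unused)
  box <- if (box_size > 0L) matrix(rd(9L) * 10, 3L, 3L, byrow = TRUE)
         else matrix(0, 3L, 3L)
  cur_take(cur, sz[4L] + sz[5L] + sz[6L] + sz[7L])  # vir/pres/top/sym
  if (x_size <= 0L) stop("TRR frame has no coordinate block")
  coords <- matrix(rd(3L * natoms) * 10, ncol = 3L, byrow = TRUE)
  cur_take(cur, v_size + f_size)  # velocities/forces skipped
  list(time = time, box = box, coords = coords, step = step)
}

#' Write a Gromacs TRR trajectory (single precision)
#'
#' Fixture-grade writer used to exercise [read_trr()] without external
#' files; emits box and position blocks only.
#'
#' @param traj a `moltraj` (coordinates in Angstrom; written as nm).
#' @param path optional output file.
#' @return raw vector of the file bytes.
#' @export
write_trr <- function(traj, path = NULL) {
  out <- lapply(seq_along(traj$frames), function(k) {
    f <- traj$frames[[k]]
    n <- nrow(f$coords)
    vs <- charToRaw(TRR_VERSION)
    c(wr_int(TRR_MAGIC), wr_int(length(vs) + 1L), wr_int(length(vs)), vs,
      raw((4L - length(vs) %% 4L) %% 4L),
      wr_int(c(0L, 0L, 36L, 0L, 0L, 0L, 0L, 12L * n, 0L, 0L)),
      wr_int(c(n, k - 1L, 0L)),
      wr_float(c(f$time, 0)),
      wr_float(as.vector(t(f$box)) / 10),
      wr_float(as.vector(t(f$coords)) / 10))
  })
  bytes <- do.call(c, out)
  if (!is.null(path)) {
    writeBin(bytes, path)
    return(invisible(bytes))
  }
  bytes
}

# --- XTC -------------------------------------------------------------------

XTC_MAGIC <- 1995L

#' Read a Gromacs XTC trajectory
#'
#' XDR big-endian frames with magic 1995. Frames of more than 9 atoms store
#' coordinates with the XTC integer-compression scheme (per-frame bounds,
#' variable bit-width packing, small-delta run-length encoding); frames of
#' 9 or fewer atoms are stored as raw floats. Coordinates and box are
#' converted nm to Angstrom on read.
#'
#' @param path file path, or `bytes` a raw vector.
#' @param bytes raw vector alternative to `path`.
#' @return a `moltraj`; each frame carries the file `precision` attribute.
#' @export
read_xtc <- function(path = NULL, bytes = NULL) {
  if (is.null(bytes)) bytes <- read_file_raw(path)
  cur <- new_cursor(bytes)
  frames <- list()
  natoms0 <- NULL
  while (cur_left(cur) >= 4L) {
    frame <- tryCatch(xtc_read_frame(cur), error = function(err) {
      stop(sprintf("XTC frame %d: %s", length(frames) + 1L,
                   conditionMessage(err)))
    })
    if (is.null(natoms0)) natoms0 <- nrow(frame$coords)
    frames[[length(frames) + 1L]] <- frame
  }
  if (!length(frames)) stop("empty XTC file")
  new_trajectory(natoms0, frames)
}

xtc_read_frame <- function(cur) {
  magic <- cur_int(cur)
  if (magic != XTC_MAGIC)
    stop(sprintf("not an XTC frame: magic %d != 1995", magic))
  natoms <- cur_int(cur)
  if (natoms < 0L || natoms > 2e8) stop("implausible atom count")
  step <- cur_int(cur)
  time <- cur_float(cur)
  box <- matrix(cur_float(cur, 9L) * 10, 3L, 3L, byrow = TRUE)
  natoms2 <- cur_int(cur)
  if (natoms2 != natoms) stop("inconsistent atom counts in frame header")
  if (natoms <= 9L) {
    xyz <- matrix(cur_float(cur, 3L * natoms), ncol = 3L, byrow = TRUE)
    prec <- NA_real_
  } else {
    prec <- cur_float(cur)
    if (!is.finite(prec) || prec <= 0) stop("invalid precision")
    minint <- cur_int(cur, 3L)
    maxint <- cur_int(cur, 3L)
    smallidx <- cur_int(cur) + 1L  # to 1-based table index
    nbytes <- cur_int(cur)
    if (nbytes < 0L || nbytes > cur_left(cur)) stop("corrupt data-block length")
    data <- cur_take(cur, nbytes)
    cur_take(cur, (4L - nbytes %% 4L) %% 4L)  # opaque padding
    xyz <- xtc_decode_coords(natoms, prec, minint, maxint, smallidx, data)
  }
  list(time = time, box = box, coords = xyz * 10, step = step,
       precision = prec)
}

#' Write a Gromacs XTC trajectory
#'
#' Inverse of [read_xtc()]; exists so the compressed reader can be tested
#' end-to-end. Every coordinate survives a write/read round trip within
#' `1/(2 * precision)` nm.
#'
#' @param traj a `moltraj` (Angstrom; written as nm).
#' @param precision coordinate quantization (file units per nm, e.g. 1000).
#' @param path optional output file.
#' @return raw vector of the file bytes.
#' @export
write_xtc <- function(traj, precision = 1000, path = NULL) {
  out <- lapply(seq_along(traj$frames), function(k) {
    f <- traj$frames[[k]]
    n <- nrow(f$coords)
    head <- c(wr_int(c(XTC_MAGIC, n, k - 1L)), wr_float(f$time),
              wr_float(as.vector(t(f$box)) / 10), wr_int(n))
    if (n <= 9L) {
      c(head, wr_float(as.vector(t(f$coords)) / 10))
    } else {
      enc <- xtc_encode_coords(f$coords / 10, precision)
      nbytes <- length(enc$data)
      c(head, wr_float(precision), wr_int(enc$minint), wr_int(enc$maxint),
        wr_int(enc$smallidx - 1L), wr_int(nbytes), enc$data,
        raw((4L - nbytes %% 4L) %% 4L))
    }
  })
  bytes <- do.call(c, out)
  if (!is.null(path)) {
    writeBin(bytes, path)
    return(invisible(bytes))
  }
  bytes
}
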