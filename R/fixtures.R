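#' @title Synthetic fixture generators
#' @description
#' Deterministic generators for every input kind the toolkit reads, so all
#' codecs, builders and the renderer are testable without external files:
#' ideal poly-alanine helices and strands built from internal coordinates,
#' matched mmCIF/PDBML/mmJSON oracle triples, analytic Gaussian density
#' maps with their CCP4 serialization, and seeded random-walk trajectories
#' with TRR/XTC bytes. Each generator is a pure function of its arguments
#' (randomness flows through one explicit seed).
#' @name synthetic-fixtures
NULL

# NeRF-style sequential internal-coordinate placement: position D with
# |CD| = r, angle(B,C,D) = theta, dihedral(A,B,C,D) = phi (degrees).
place_atom <- function(A, B, C, r, theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- vcross(ab, bc)
  nl <- sqrt(sum(n^2))
  if (nl < 1e-9) {        # collinear history: pick any perpendicular
    n <- vcross(bc, perpendicular_unit(bc))
    nl <- sqrt(sum(n^2))
  }
  n <- n / nl
  m <- vcross(n, bc)
  d2 <- c(-r * cos(th), r * sin(th) * cos(ph), -r * sin(th) * sin(ph))
  C + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

# standard backbone geometry (Angstrom / degrees)
BB_N_CA <- 1.458; BB_CA_C <- 1.525; BB_C_N <- 1.329
BB_ANG_N_CA_C <- 111.2; BB_ANG_CA_C_N <- 116.2; BB_ANG_C_N_CA <- 121.7

#' Ideal poly-alanine backbone from internal coordinates
#'
#' Builds an N-CA-C backbone by sequential torsion placement with standard
#' bond lengths (N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom) and angles,
#' at the requested phi/psi/omega. The defaults give an ideal alpha helix
#' (consecutive CA-CA distance 3.8, rise per residue 1.5 Angstrom).
#'
#' @param n_residues chain length (>= 2).
#' @param phi,psi,omega backbone dihedrals in degrees.
#' @param chain chain identifier.
#' @return a `molstruct` (secondary structure left as assigned by the
#'   dihedral heuristic).
#' @export
make_ideal_helix <- function(n_residues, phi = -57, psi = -47, omega = 180,
                             chain = "A") {
  stopifnot(n_residues >= 2L)
  n <- n_residues
  pos <- matrix(0, 3L * n, 3L)
  # residue 1 in a canonical frame
  pos[1L, ] <- c(0, 0, 0)                       # N1
  pos[2L, ] <- c(BB_N_CA, 0, 0)                 # CA1
  ang <- BB_ANG_N_CA_C * pi / 180
  pos[3L, ] <- pos[2L, ] + BB_CA_C * c(-cos(ang), sin(ang), 0)  # C1
  for (i in 2:n) {
    b <- 3L * (i - 1L)
    Np <- pos[b - 2L, ]; CAp <- pos[b - 1L, ]; Cp <- pos[b, ]
    pos[b + 1L, ] <- place_atom(Np, CAp, Cp, BB_C_N, BB_ANG_CA_C_N, psi)
    pos[b + 2L, ] <- place_atom(CAp, Cp, pos[b + 1L, ], BB_N_CA,
                                BB_ANG_C_N_CA, omega)
    pos[b + 3L, ] <- place_atom(Cp, pos[b + 1L, ], pos[b + 2L, ], BB_CA_C,
                                BB_ANG_N_CA_C, phi)
  }
  atoms <- data.frame(
    serial = seq_len(3L * n),
    name = rep(c("N", "CA", "C"), n),
    element = rep(c("N", "C", "C"), n),
    alt_loc = "", is_hetero = FALSE, comp_id = "ALA",
    seq_id = rep(seq_len(n), each = 3L), ins_code = "",
    asym_id = chain, auth_asym_id = chain, occupancy = 1, b_factor = 0,
    stringsAsFactors = FALSE)
  st <- new_structure(atoms, list(pos), entry_id = "HELIX")
  assign_secondary_structure(st)
}

#' Matched mmCIF / PDBML / mmJSON oracle triple
#'
#' Emits three representations of one small entry (cell parameters plus a
#' short atom_site table with null cells), used as the cross-codec oracle:
#' parsing any of the three must produce the same data model.
#'
#' @param entry entry id used as the block name.
#' @return list with elements `mmcif`, `pdbml`, `mmjson` (document strings).
#' @export
make_toy_mmcif <- function(entry = "TOY") {
  mmcif <- paste0(
    "data_", entry, "\n",
    "_cell.length_a   24.5\n",
    "_cell.length_b   30\n",
    "_cell.angle_alpha 90\n",
    "_entry.id '", entry, "'\n",
    "loop_\n",
    "_atom_site.id\n",
    "_atom_site.group_PDB\n",
    "_atom_site.type_symbol\n",
    "_atom_site.label_atom_id\n",
    "_atom_site.label_comp_id\n",
    "_atom_site.label_asym_id\n",
    "_atom_site.auth_asym_id\n",
    "_atom_site.label_seq_id\n",
    "_atom_site.auth_seq_id\n",
    "_atom_site.Cartn_x\n",
    "_atom_site.Cartn_y\n",
    "_atom_site.Cartn_z\n",
    "_atom_site.occupancy\n",
    "_atom_site.B_iso_or_equiv\n",
    "_atom_site.pdbx_PDB_model_num\n",
    "1 ATOM N N ALA A A 1 1 11.104 6.134 2.229 1 10.5 1\n",
    "2 ATOM C CA ALA A A 1 1 12.56 6.071 2.3 1 ? 1\n",
    "3 ATOM C C ALA A A 1 1 13.123 7.481 2.5 0.5 12 1\n",
    "4 ATOM N N GLY A A 2 2 12.9 8.434 1.8 1 9 1\n",
    "5 ATOM C CA GLY A A 2 2 13.45 9.78 1.7 1 ? 1\n")
  rows <- list(
    list(g = "ATOM", id = 1L, ts = "N", an = "N", cn = "ALA", sq = 1L,
         x = 11.104, y = 6.134, z = 2.229, occ = 1L, b = "10.5"),
    list(g = "ATOM", id = 2L, ts = "C", an = "CA", cn = "ALA", sq = 1L,
         x = 12.56, y = 6.071, z = 2.3, occ = 1L, b = NULL),
    list(g = "ATOM", id = 3L, ts = "C", an = "C", cn = "ALA", sq = 1L,
         x = 13.123, y = 7.481, z = 2.5, occ = "0.5", b = 12L),
    list(g = "ATOM", id = 4L, ts = "N", an = "N", cn = "GLY", sq = 2L,
         x = 12.9, y = 8.434, z = 1.8, occ = 1L, b = 9L),
    list(g = "ATOM", id = 5L, ts = "C", an = "CA", cn = "GLY", sq = 2L,
         x = 13.45, y = 9.78, z = 1.7, occ = 1L, b = NULL))
  fmt <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) x else format(x)
  }
  xml_rows <- vapply(rows, function(r) {
    b <- if (is.null(r$b)) "" else paste0("      <PDBx:B_iso_or_equiv>",
                                          fmt(r$b), "</PDBx:B_iso_or_equiv>\n")
    paste0(
      "    <PDBx:atom_site id=\"", r$id, "\">\n",
      "      <PDBx:group_PDB>", r$g, "</PDBx:group_PDB>\n",
      "      <PDBx:type_symbol>", r$ts, "</PDBx:type_symbol>\n",
      "      <PDBx:label_atom_id>", r$an, "</PDBx:label_atom_id>\n",
      "      <PDBx:label_comp_id>", r$cn, "</PDBx:label_comp_id>\n",
      "      <PDBx:label_asym_id>A</PDBx:label_asym_id>\n",
      "      <PDBx:auth_asym_id>A</PDBx:auth_asym_id>\n",
      "      <PDBx:label_seq_id>", r$sq, "</PDBx:label_seq_id>\n",
      "      <PDBx:auth_seq_id>", r$sq, "</PDBx:auth_seq_id>\n",
      "      <PDBx:Cartn_x>", fmt(r$x), "</PDBx:Cartn_x>\n",
      "      <PDBx:Cartn_y>", fmt(r$y), "</PDBx:Cartn_y>\n",
      "      <PDBx:Cartn_z>", fmt(r$z), "</PDBx:Cartn_z>\n",
      "      <PDBx:occupancy>", fmt(r$occ), "</PDBx:occupancy>\n",
      b,
      "      <PDBx:pdbx_PDB_model_num>1</PDBx:pdbx_PDB_model_num>\n",
      "    </PDBx:atom_site>\n")
  }, "")
  pdbml <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<PDBx:datablock datablockName=\"", entry, "\"\n",
    "  xmlns:PDBx=\"http://pdbml.pdb.org/schema/pdbx-v50.xsd\"\n",
    "  xmlns:xsi=\"http://www.w3.org/2001/XMLSchema-instance\">\n",
    "  <PDBx:cellCategory>\n",
    "    <PDBx:cell>\n",
    "      <PDBx:length_a>24.5</PDBx:length_a>\n",
    "      <PDBx:length_b>30</PDBx:length_b>\n",
    "      <PDBx:angle_alpha>90</PDBx:angle_alpha>\n",
    "    </PDBx:cell>\n",
    "  </PDBx:cellCategory>\n",
    "  <PDBx:entryCategory>\n",
    "    <PDBx:entry id=\"", entry, "\"/>\n",
    "  </PDBx:entryCategory>\n",
    "  <PDBx:atom_siteCategory>\n",
    paste(xml_rows, collapse = ""),
    "  </PDBx:atom_siteCategory>\n",
    "</PDBx:datablock>\n")
  mmjson <- to_mmjson(parse_mmcif(mmcif))
  list(mmcif = mmcif, pdbml = pdbml, mmjson = mmjson)
}

#' Analytic Gaussian-sum density map with CCP4 serialization
#'
#' @param centers k x 3 matrix of Gaussian centres (Angstrom).
#' @param sigma Gaussian width (Angstrom).
#' @param spacing grid spacing (Angstrom).
#' @param pad padding around the centres (Angstrom).
#' @return list with `grid` (a `volgrid`) and `bytes` (CCP4 mode-2 file
#'   bytes; header statistics computed from the data).
#' @export
make_gaussian_map <- function(centers, sigma = 1.5, spacing = 0.5, pad = 5) {
  centers <- matrix(centers, ncol = 3L)
  lo <- spacing * floor((apply(centers, 2L, min) - pad) / spacing)
  hi <- apply(centers, 2L, max) + pad
  dims <- pmax(as.integer(ceiling((hi - lo) / spacing)) + 1L, 2L)
  gx <- lo[1L] + spacing * (seq_len(dims[1L]) - 1L)
  gy <- lo[2L] + spacing * (seq_len(dims[2L]) - 1L)
  gz <- lo[3L] + spacing * (seq_len(dims[3L]) - 1L)
  field <- array(0, dims)
  for (k in seq_len(nrow(centers))) {
    ex <- exp(-(gx - centers[k, 1L])^2 / (2 * sigma^2))
    ey <- exp(-(gy - centers[k, 2L])^2 / (2 * sigma^2))
    ez <- exp(-(gz - centers[k, 3L])^2 / (2 * sigma^2))
    field <- field + outer(ex, outer(ey, ez))
  }
  vals <- as.vector(field)
  # store as float32 so header stats match the data as read back
  vals <- readBin(writeBin(vals, raw(), size = 4L, endian = "little"),
                  "double", length(vals), size = 4L, endian = "little")
  grid <- structure(list(
    dims = dims, axis_order = 1:3, start = as.integer(round(lo / spacing)),
    sampling = dims,
    cell = c(dims * spacing, 90, 90, 90),
    values = vals,
    stats = c(min = min(vals), max = max(vals), mean = mean(vals)),
    mode = 2L, origin = lo), class = "volgrid")
  list(grid = grid, bytes = write_ccp4(grid))
}

# run a block of code with a private, seeded RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Seeded random-walk trajectory with TRR and XTC bytes
#'
#' Frame k+1 adds independent Gaussian displacements of standard deviation
#' `step_sigma` (Angstrom) to frame k. The same seed always yields
#' byte-identical TRR/XTC files.
#'
#' @param n_atoms,n_frames sizes (>= 1).
#' @param step_sigma per-coordinate step standard deviation (Angstrom).
#' @param seed RNG seed.
#' @param precision XTC precision.
#' @return list with `traj` (a `moltraj`), `trr` and `xtc` (raw bytes).
#' @export
make_random_walk_trajectory <- function(n_atoms = 20L, n_frames = 5L,
                                        step_sigma = 0.5, seed = 1L,
                                        precision = 1000) {
  with_seed(seed, {
    box <- diag(3) * 30
    coords <- matrix(runif(n_atoms * 3L, 5, 25), ncol = 3L)
    frames <- vector("list", n_frames)
    for (k in seq_len(n_frames)) {
      if (k > 1L)
        coords <- coords + matrix(rnorm(n_atoms * 3L, 0, step_sigma), ncol = 3L)
      frames[[k]] <- list(time = (k - 1L) * 1.0, box = box, coords = coords)
    }
    traj <- new_trajectory(n_atoms, frames)
    list(traj = traj, trr = write_trr(traj),
         xtc = write_xtc(traj, precision = precision))
  })
}

# Random STAR data block for codec property tests (seeded by caller's RNG).
random_datablock <- function(max_cats = 4L, max_cols = 4L, max_rows = 6L) {
  rand_name <- function(n = 1L)
    vapply(seq_len(n), function(i)
      paste(sample(letters, sample(3:8, 1L), replace = TRUE), collapse = ""), "")
  rand_cell <- function() {
    switch(sample(5L, 1L),
      sample(-1e6:1e6, 1L),                          # integer
      signif(stats::rnorm(1, 0, 100), 10),           # real
      paste(sample(c(letters, LETTERS, " ", "'", "\"", "_", "?", ".", "0":"9"),
                   sample(1:12, 1L), replace = TRUE), collapse = ""),
      NULL,                                          # null
      sample(c("007", "A1", "N/A", "1crn", "x y"), 1L))
  }
  ncat <- sample(seq_len(max_cats), 1L)
  cats <- lapply(seq_len(ncat), function(ci) {
    ncol <- sample(seq_len(max_cols), 1L)
    nrow <- sample(seq_len(max_rows), 1L)  # mmCIF cannot express 0-row tables
    cols <- lapply(seq_len(ncol), function(j)
      lapply(seq_len(nrow), function(r) rand_cell()))
    names(cols) <- make.unique(rand_name(ncol), sep = "x")
    cif_category(rand_name(), cols)
  })
  # unique category names
  nms <- make.unique(vapply(cats, function(x) x$name, ""), sep = "x")
  for (i in seq_along(cats)) cats[[i]]$name <- nms[[i]]
  cif_block(paste0("B", paste(sample(c(LETTERS, 0:9), 4L, replace = TRUE),
                              collapse = "")), cats)
}
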