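pdb_atom_line <- function(serial, name, resn, chain, resi, x, y, z,
                          record = "ATOM", element = "C") {
  sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, resn, chain, resi, x, y, z, 1, 0, element)
}

test_that("legacy PDB fixed columns parse at the standard offsets", {
  line <- pdb_atom_line(1, "CA", "ALA", "A", 1, 11.104, 6.134, 2.229)
  st <- parse_pdb(c(line, "END"))
  expect_equal(n_atoms(st), 1L)
  expect_equal(st$atoms$element, "C")
  expect_equal(st$atoms$name, "CA")
  expect_equal(st$coords[[1]][1, ], c(11.104, 6.134, 2.229))
  # HETATM water
  w <- parse_pdb(pdb_atom_line(1, "O", "HOH", "A", 1, 0, 0, 0,
                               record = "HETATM", element = "O"))
  expect_true(w$atoms$is_hetero)
  expect_equal(w$chains$moltype, "other")
  # non-numeric coordinate -> line-numbered error
  bad <- sub("11.104", "x1.104", line, fixed = TRUE)
  expect_error(parse_pdb(bad), "line 1")
})

test_that("PDB MODEL records split equal-sized models and HELIX feeds ss", {
  lines <- c(
    "MODEL        1",
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 2, 3.8, 0, 0),
    "ENDMDL",
    "MODEL        2",
    pdb_atom_line(1, "CA", "ALA", "A", 1, 1, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 2, 4.8, 0, 0),
    "ENDMDL")
  st <- parse_pdb(lines)
  expect_equal(length(st$coords), 2L)
  expect_equal(n_atoms(st), 2L)
  helix <- c("HELIX    1   1 ALA A    1  ALA A    2  1",
             pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
             pdb_atom_line(2, "CA", "ALA", "A", 2, 3.8, 0, 0))
  st2 <- parse_pdb(helix)
  expect_equal(st2$residues$ss, c("helix", "helix"))
  # unequal model sizes rejected
  bad <- c("MODEL 1", pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
           "ENDMDL", "MODEL 2",
           pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
           pdb_atom_line(2, "CA", "ALA", "A", 2, 3.8, 0, 0), "ENDMDL")
  expect_error(parse_pdb(bad), "model")
})

test_that("GRO parsing converts nm to Angstrom exactly once", {
  gro <- c("box of nothing", " 3",
           "    1ALA      N    1   0.100   0.200   0.300",
           "    1ALA     CA    2   0.500   0.000   0.000",
           "    2SOL     OW    3   1.000   1.000   1.000",
           "   2.0   2.0   2.0")
  st <- parse_gro(gro)
  expect_equal(st$coords[[1]][2, 1], 5.0)            # 0.5 nm -> 5 A
  expect_equal(st$coords[[1]][3, ], c(10, 10, 10))   # 1 nm distance -> 10 A
  expect_equal(diag(attr(st, "box")), c(20, 20, 20))
  expect_error(parse_gro(gro[1:4]), "box|atom lines")
  gro_bad <- gro; gro_bad[2] <- " 9"
  expect_error(parse_gro(gro_bad), "declares")
})

test_that("MOL2 sections give atoms, elements and explicit bonds", {
  mol2 <- c("@<TRIPOS>MOLECULE", "ethane frag", " 2 1", "SMALL", "NO_CHARGES",
            "@<TRIPOS>ATOM",
            " 1 C1 0.0 0.0 0.0 C.3 1 LIG",
            " 2 N1 1.5 0.0 0.0 N.ar 1 LIG",
            "@<TRIPOS>BOND", " 1 1 2 1")
  st <- parse_mol2(mol2)
  expect_equal(n_atoms(st), 2L)
  expect_equal(st$atoms$element, c("C", "N"))        # SYBYL type -> element
  expect_identical(st$bonds, matrix(c(1L, 2L), 1))
  expect_identical(structure_bonds(st), st$bonds)    # explicit overrides
  expect_error(parse_mol2("@<TRIPOS>MOLECULE\nx\n1 0"), "ATOM")
})

test_that("MDL V2000 counts line and blocks parse at fixed columns", {
  mdl <- c("title", "", "",
           "  2  1  0  0  0  0  0  0  0  0999 V2000",
           "    0.0000    0.0000    0.0000 C   0  0",
           "    1.5000    0.0000    0.0000 O   0  0",
           "  1  2  1  0")
  st <- parse_mdl(mdl)
  expect_equal(n_atoms(st), 2L)
  expect_equal(st$atoms$element, c("C", "O"))
  expect_identical(st$bonds, matrix(c(1L, 2L), 1))
  expect_error(parse_mdl(mdl[1:5]), "truncated")
})

test_that("CCP4 round trip, header semantics and statistics", {
  mp <- make_gaussian_map(rbind(c(0, 0, 0), c(4, 0, 0)), sigma = 1.2,
                          spacing = 1)
  g <- read_ccp4(bytes = mp$bytes)
  expect_identical(g$values, mp$grid$values)              # bit-exact
  expect_equal(g$stats[["mean"]], mean(g$values), tolerance = 1e-5)
  expect_equal(g$dims, mp$grid$dims)
  expect_equal(g$axis_order, 1:3)
  # axis order is read from MAPC/MAPR/MAPS
  bytes <- mp$bytes
  bytes[65:76] <- writeBin(c(2L, 1L, 3L), raw(), size = 4, endian = "little")
  g2 <- read_ccp4(bytes = bytes)
  expect_equal(g2$axis_order, c(2L, 1L, 3L))
  # unsupported mode -> error naming it
  bad <- mp$bytes
  bad[13:16] <- writeBin(6L, raw(), size = 4, endian = "little")
  expect_error(read_ccp4(bytes = bad), "mode 6")
  # truncation detected
  expect_error(read_ccp4(bytes = mp$bytes[1:2000]), "truncated")
})

test_that("TRR reader decodes reference bytes from an independent writer", {
  tr <- read_trr(bytes = decode_b64(ref_trr_b64))
  expect_equal(length(tr$frames), 2L)
  expect_equal(tr$n_atoms, 5L)
  expect_equal(tr$frames[[1]]$coords / 10, ref_trr_frame1, tolerance = 1e-6)
  expect_equal(tr$frames[[2]]$coords / 10, ref_trr_frame2, tolerance = 1e-6)
  expect_equal(tr$frames[[2]]$time, 2.0)
  expect_equal(tr$frames[[1]]$box, diag(3) * 20, tolerance = 1e-6)
})

test_that("TRR write/read round trip preserves coordinates to 6 decimals", {
  fx <- make_random_walk_trajectory(n_atoms = 12, n_frames = 3, seed = 11)
  back <- read_trr(bytes = fx$trr)
  expect_equal(length(back$frames), 3L)
  for (k in 1:3) {
    expect_lt(max(abs(back$frames[[k]]$coords - fx$traj$frames[[k]]$coords)),
              1e-4)  # float32 storage of nm values
    expect_equal(back$frames[[k]]$time, fx$traj$frames[[k]]$time)
  }
  expect_error(read_trr(bytes = as.raw(c(0, 0, 0, 9, 1, 2, 3, 4))), "1993")
})

test_that("XTC reader decodes reference bytes from an independent writer", {
  x <- read_xtc(bytes = decode_b64(ref_xtc20_b64))
  expect_equal(x$n_atoms, 20L)
  expect_equal(x$frames[[1]]$time, 1.5)
  err <- max(abs(x$frames[[1]]$coords / 10 - ref_xtc20_frame))
  expect_lte(err, 0.0005 + 1e-9)       # half a quantum at precision 1000
})

test_that("XTC round trip respects the quantization bound per precision", {
  for (prec in c(100, 1000, 10000)) {
    fx <- make_random_walk_trajectory(n_atoms = 30, n_frames = 2, seed = 3,
                                      precision = prec)
    back <- read_xtc(bytes = fx$xtc)
    bound <- 10 / (2 * prec)  # Angstrom
    for (k in 1:2)
      expect_lte(max(abs(back$frames[[k]]$coords -
                         fx$traj$frames[[k]]$coords)), bound + 1e-9)
  }
  # <= 9 atoms stored uncompressed: float32-exact round trip
  small <- make_random_walk_trajectory(n_atoms = 5, n_frames = 1, seed = 4)
  sb <- read_xtc(bytes = small$xtc)
  expect_lt(max(abs(sb$frames[[1]]$coords - small$traj$frames[[1]]$coords)),
            1e-4)
  expect_error(read_xtc(bytes = as.raw(c(0, 0, 7, 0, 1, 2, 3, 4))), "1995")
})

test_that("binary readers reject headers mutated at random bytes", {
  set.seed(17)
  fx <- make_random_walk_trajectory(n_atoms = 15, n_frames = 1, seed = 8)
  mp <- make_gaussian_map(rbind(c(0, 0, 0)), spacing = 1.5)
  cases <- list(
    list(bytes = fx$trr, read = function(b) read_trr(bytes = b)),
    list(bytes = fx$xtc, read = function(b) read_xtc(bytes = b)),
    list(bytes = mp$bytes, read = function(b) read_ccp4(bytes = b)))
  for (cs in cases) {
    clean <- cs$read(cs$bytes)
    rejected <- 0L
    for (rep in 1:12) {
      b <- cs$bytes
      pos <- sample(4L, 1L)                 # corrupt the magic/first word
      b[pos] <- as.raw(bitwXor(as.integer(b[pos]), 0xffL))
      got <- tryCatch({ cs$read(b); FALSE }, error = function(e) TRUE,
                      warning = function(w) TRUE)
      rejected <- rejected + got
    }
    expect_gte(rejected, 11L)  # flipping high bytes of the magic must fail
  }
})

test_that("multi-model structures convert to trajectories bit-exactly", {
  cif_rows <- unlist(lapply(1:5, function(m) sprintf(
    "ATOM %d C CA ALA A 1 %g 0 0 %d", m, m * 1.0, m)))
  cif <- paste0("data_N\nloop_\n_atom_site.group_PDB\n_atom_site.id\n",
                "_atom_site.type_symbol\n_atom_site.label_atom_id\n",
                "_atom_site.label_comp_id\n_atom_site.label_asym_id\n",
                "_atom_site.auth_seq_id\n_atom_site.Cartn_x\n",
                "_atom_site.Cartn_y\n_atom_site.Cartn_z\n",
                "_atom_site.pdbx_PDB_model_num\n",
                paste(cif_rows, collapse = "\n"), "\n")
  st <- build_structure(parse_mmcif(cif))
  expect_equal(length(st$coords), 5L)
  traj <- structure_to_trajectory(st)
  expect_equal(length(traj$frames), 5L)
  for (k in 1:5)
    expect_identical(traj$frames[[k]]$coords, st$coords[[k]])
  one <- structure_to_trajectory(tiny_structure())
  expect_equal(length(one$frames), 1L)
})

test_that("PDB parsing agrees with an independent reader on a fixture", {
  td <- withr::local_tempdir()
  f <- file.path(td, "x.pdb")
  lines <- c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 11.104, 6.134, 2.229, element = "N"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 12.560, 6.071, 2.300),
    pdb_atom_line(3, "C", "ALA", "A", 1, 13.123, 7.481, 2.500),
    pdb_atom_line(4, "O", "HOH", "B", 101, -4.250, 0.125, 9.875,
                  record = "HETATM", element = "O"),
    "END")
  writeLines(lines, f)
  st <- parse_pdb(path = f)
  ref <- bio3d::read.pdb(f)
  expect_equal(unname(st$coords[[1]]),
               unname(as.matrix(ref$atom[, c("x", "y", "z")])))
  expect_equal(st$atoms$name, ref$atom$elety)
  expect_equal(st$atoms$comp_id, ref$atom$resid)
  expect_equal(st$atoms$seq_id, ref$atom$resno)
  expect_equal(st$atoms$is_hetero, ref$atom$type == "HETATM")
})
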