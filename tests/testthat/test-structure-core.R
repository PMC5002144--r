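test_that("build_structure groups chains, models and applies alt-loc policy", {
  cif <- paste0(
    "data_X\nloop_\n",
    "_atom_site.group_PDB\n_atom_site.id\n_atom_site.type_symbol\n",
    "_atom_site.label_atom_id\n_atom_site.label_comp_id\n",
    "_atom_site.label_asym_id\n_atom_site.auth_seq_id\n",
    "_atom_site.label_alt_id\n_atom_site.occupancy\n",
    "_atom_site.Cartn_x\n_atom_site.Cartn_y\n_atom_site.Cartn_z\n",
    "_atom_site.pdbx_PDB_model_num\n",
    "ATOM 1 C CA ALA A 1 A 0.6 0 0 0 1\n",
    "ATOM 2 C CA ALA A 1 B 0.4 1 0 0 1\n",
    "ATOM 3 C CA ALA B 1 . 1.0 5 0 0 1\n",
    "ATOM 4 C CA ALA A 1 A 0.6 0 0 1 2\n",
    "ATOM 5 C CA ALA A 1 B 0.4 1 0 1 2\n",
    "ATOM 6 C CA ALA B 1 . 1.0 5 0 1 2\n")
  st <- build_structure(parse_mmcif(cif))
  expect_equal(nrow(st$chains), 2L)
  expect_equal(length(st$coords), 2L)
  expect_equal(n_atoms(st), 2L)           # alt B dropped per model
  expect_equal(st$atoms$alt_loc, c("A", ""))  # "." alt-loc is "no alternate"
  expect_equal(st$coords[[2]][, 3], c(1, 1))
  expect_error(build_structure(parse_mmcif("data_X\n_atom_site.id 1\n")),
               "Cartn")
})

test_that("atom counts are conserved through the hierarchy", {
  st <- tiny_structure()
  expect_equal(sum(table(st$atoms$residue_index)), n_atoms(st))
  expect_equal(nrow(st$residues), 5L)
  expect_equal(nrow(st$chains), 2L)
  expect_equal(st$chains$moltype, c("polypeptide", "polypeptide"))
})

test_that("secondary structure from annotations overrides the heuristic", {
  st <- make_ideal_helix(10)
  ranges <- data.frame(kind = "helix", asym_id = "A", beg = 2, end = 8,
                       stringsAsFactors = FALSE)
  st2 <- assign_secondary_structure(st, ranges)
  expect_equal(st2$residues$ss[2:8], rep("helix", 7))
  expect_equal(st2$residues$ss[c(1, 9, 10)], rep("coil", 3))
  # idempotence
  st3 <- assign_secondary_structure(st2, ranges)
  expect_identical(st3$residues$ss, st2$residues$ss)
})

test_that("dihedral heuristic marks ideal helices and strands", {
  hel <- make_ideal_helix(8)                       # phi -57 / psi -47
  expect_true(all(hel$residues$ss[3:6] == "helix"))
  sheet <- make_ideal_helix(8, phi = -120, psi = 130)
  expect_true(all(sheet$residues$ss[3:6] == "sheet"))
  short <- make_ideal_helix(2)
  expect_true(all(short$residues$ss == "coil"))
  # idempotence of the heuristic path
  again <- assign_secondary_structure(hel)
  expect_identical(again$residues$ss, hel$residues$ss)
})

test_that("bond inference follows the covalent-radius rule", {
  mk <- function(d) {
    atoms <- data.frame(serial = 1:2, name = "C", element = "C", alt_loc = "",
                        is_hetero = FALSE, comp_id = "LIG", seq_id = 1L,
                        ins_code = "", asym_id = "A", auth_asym_id = "A",
                        occupancy = 1, b_factor = 0, stringsAsFactors = FALSE)
    new_structure(atoms, list(rbind(c(0, 0, 0), c(d, 0, 0))))
  }
  expect_equal(nrow(infer_bonds(mk(1.54))), 1L)    # 1.54 <= 0.76+0.76+0.45
  expect_equal(nrow(infer_bonds(mk(3.0))), 0L)
  expect_equal(nrow(infer_bonds(mk(0.3))), 0L)     # overlapping duplicates
})

test_that("grid bond search agrees with the brute-force oracle", {
  for (seed in 1:6) {
    st <- random_carbon_structure(100, spread = 10, seed = seed)
    grid <- infer_bonds(st)
    brute <- molviewr:::infer_bonds_brute(st)
    expect_identical(grid, brute)
    # symmetric, self-loop-free by construction (i < j)
    if (nrow(grid)) expect_true(all(grid[, 1] < grid[, 2]))
  }
})

test_that("selection grammar implements the documented term semantics", {
  st <- tiny_structure()
  expect_equal(as.integer(select_atoms(st, "chain A")), 1:6)
  expect_equal(as.integer(select_atoms(st, "chain A and resi 10-11")), 1:4)
  expect_equal(as.integer(select_atoms(st, "resn HOH")), 6L)
  expect_equal(as.integer(select_atoms(st, "name CA and not hetero")),
               c(2L, 4L, 5L, 7L))
  expect_equal(as.integer(select_atoms(st, "hetero or chain B")), c(6L, 7L))
  expect_equal(as.integer(select_atoms(st, "(chain B or resi 12) and polymer")),
               c(5L, 7L))
  expect_error(select_atoms(st, "chain A and flub x"), "syntax error")
  expect_error(select_atoms(st, "chain A and (resi 1"), "\\)")
})

test_that("selection algebra satisfies complement and De Morgan laws", {
  st <- tiny_structure()
  all_idx <- seq_len(n_atoms(st))
  u <- union(as.integer(select_atoms(st, "not hetero")),
             as.integer(select_atoms(st, "hetero")))
  expect_equal(sort(u), all_idx)
  a <- "resn ALA"; b <- "name CA"
  lhs <- as.integer(select_atoms(st, sprintf("not (%s or %s)", a, b)))
  rhs <- intersect(as.integer(select_atoms(st, sprintf("not %s", a))),
                   as.integer(select_atoms(st, sprintf("not %s", b))))
  expect_equal(lhs, sort(rhs))
  expect_equal(as.integer(select_atoms(st, "resn ALA or resn GLY")),
               sort(union(as.integer(select_atoms(st, "resn ALA")),
                          as.integer(select_atoms(st, "resn GLY")))))
})

test_that("focus_target returns the centroid and bounding radius", {
  st <- tiny_structure()
  f1 <- focus_target(st, 1L)
  expect_equal(f1$center, c(0, 0, 0))
  expect_equal(f1$radius, 0)
  atoms2 <- st$coords[[1]][c(1, 2), ]
  f2 <- focus_target(st, c(1L, 2L))
  expect_equal(f2$center, colMeans(atoms2))
  expect_equal(f2$radius, 0.73)
  expect_error(focus_target(st, integer(0)), "empty")
  # radius equals brute-force max distance from centroid
  set.seed(5)
  st2 <- random_carbon_structure(50)
  f3 <- focus_target(st2, NULL)
  co <- st2$coords[[1]]
  expect_equal(f3$radius,
               sqrt(max(rowSums(sweep(co, 2, colMeans(co))^2))))
})
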