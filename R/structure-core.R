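#' @title Molecular structure model
#' @description
#' A `molstruct` holds one topology shared by one or more coordinate models:
#' an atom table, residue and chain tables, per-model coordinate matrices
#' (always in Angstrom) and an optional bond list. All readers (mmCIF,
#' mmJSON, PDBML, PDB, GRO, MOL2, MDL) land in this type.
#' @name molstruct
NULL

# Cordero single-bond covalent radii (Angstrom); used by infer_bonds().
COVALENT_RADII <- c(H = 0.31, D = 0.31, B = 0.84, C = 0.76, N = 0.71,
                    O = 0.66, F = 0.57, SI = 1.11, P = 1.07, S = 1.05,
                    CL = 1.02, BR = 1.20, I = 1.39, FE = 1.32, ZN = 1.22,
                    MG = 1.41, CA = 1.76, "NA" = 1.66, K = 2.03, MN = 1.39,
                    CU = 1.32, NI = 1.24, CO = 1.26, SE = 1.20)
COVALENT_DEFAULT <- 0.77
BOND_TOL <- 0.45          # added to radius sum
BOND_MIN <- 0.4           # below this, treated as overlapping duplicates

# Bondi van der Waals radii (Angstrom); default 1.7 for unknown elements.
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, FE = 1.80,
               ZN = 1.39, MG = 1.73, CA = 2.00, "NA" = 2.27, K = 2.75)
VDW_DEFAULT <- 1.7

AMINO_ACIDS <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
                 "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL",
                 "MSE","SEC","PYL")
NUCLEOTIDES <- c("A","C","G","U","I","DA","DC","DG","DT","DU","DI")

covalent_radius <- function(element) {
  r <- COVALENT_RADII[toupper(element)]
  r[is.na(r)] <- COVALENT_DEFAULT
  unname(r)
}

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- VDW_DEFAULT
  unname(r)
}

# Element from an atom name when no type_symbol is available: strip digits
# and primes, try a two-letter symbol, fall back to the first letter.
infer_element <- function(name) {
  vapply(name, function(nm) {
    s <- gsub("[^A-Za-z]", "", nm)
    if (!nzchar(s)) return("C")
    two <- toupper(substr(s, 1L, 2L))
    one <- toupper(substr(s, 1L, 1L))
    if (one %in% c("C", "N", "O", "S", "P", "H")) return(one)
    if (two %in% names(COVALENT_RADII)) return(two)
    one
  }, "", USE.NAMES = FALSE)
}

#' Construct a structure from component tables
#'
#' Low-level constructor used by every reader. Groups atoms into residues
#' (consecutive runs of identical chain/residue identifiers, preserving file
#' order) and residues into chains, classifies chain molecule types, and
#' validates model coordinate shapes.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `alt_loc`, `is_hetero`, `comp_id`, `seq_id`, `ins_code`, `asym_id`,
#'   `auth_asym_id`, `occupancy`, `b_factor`.
#' @param coords list of `n x 3` numeric matrices (one per model, Angstrom).
#' @param entry_id entry identifier string.
#' @param bonds optional 2-column integer matrix of 1-based atom indices.
#' @return an object of class `molstruct`.
#' @export
new_structure <- function(atoms, coords, entry_id = "", bonds = NULL) {
  stopifnot(is.data.frame(atoms), is.list(coords), length(coords) >= 1L)
  n <- nrow(atoms)
  for (m in coords) {
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != 3L)
      stop("all models must be n x 3 coordinate matrices matching the atom table")
    if (any(!is.finite(m))) stop("non-finite coordinates")
  }
  if (any(!nzchar(atoms$element))) stop("atoms with empty element symbol")
  # residue grouping: run-length over the residue identity key, file order
  key <- paste(atoms$asym_id, atoms$seq_id, atoms$ins_code, atoms$comp_id,
               sep = "\r")
  ridx <- cumsum(c(TRUE, key[-1L] != key[-n]))
  atoms$residue_index <- ridx
  first <- which(c(TRUE, key[-1L] != key[-n]))
  residues <- data.frame(
    comp_id = atoms$comp_id[first],
    seq_id = atoms$seq_id[first],
    ins_code = atoms$ins_code[first],
    asym_id = atoms$asym_id[first],
    auth_asym_id = atoms$auth_asym_id[first],
    ss = "coil",
    stringsAsFactors = FALSE)
  ck <- residues$asym_id
  cidx <- cumsum(c(TRUE, ck[-1L] != ck[-length(ck)]))
  residues$chain_index <- cidx
  cfirst <- which(c(TRUE, ck[-1L] != ck[-length(ck)]))
  chains <- data.frame(
    asym_id = residues$asym_id[cfirst],
    auth_asym_id = residues$auth_asym_id[cfirst],
    stringsAsFactors = FALSE)
  chains$moltype <- vapply(seq_len(nrow(chains)), function(ci) {
    comp <- residues$comp_id[residues$chain_index == ci]
    if (mean(comp %in% AMINO_ACIDS) > 0.5) "polypeptide"
    else if (mean(comp %in% NUCLEOTIDES) > 0.5) "nucleic"
    else "other"
  }, "")
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2L)
    if (nrow(bonds) && (min(bonds) < 1L || max(bonds) > n))
      stop("bond indices out of range")
  }
  structure(list(entry_id = entry_id, atoms = atoms, residues = residues,
                 chains = chains, coords = coords, bonds = bonds),
            class = "molstruct")
}

#' @export
print.molstruct <- function(x, ...) {
  cat(sprintf("<molstruct> %s: %d atoms, %d residues, %d chains, %d model(s)%s\n",
              if (nzchar(x$entry_id)) x$entry_id else "(unnamed)",
              nrow(x$atoms), nrow(x$residues), nrow(x$chains),
              length(x$coords),
              if (is.null(x$bonds)) "" else sprintf(", %d bonds", nrow(x$bonds))))
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure a `molstruct`.
#' @return integer atom count (per model).
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' Build a structure from parsed PDBx blocks
#'
#' Maps the `atom_site` category of the first block onto the structure model:
#' models split on `pdbx_PDB_model_num`, chains on `label_asym_id`, elements
#' from `type_symbol` (inferred from the atom name when absent), and
#' alternate locations reduced to a single conformer by keeping the highest
#' occupancy (alphabetically first alt_loc on ties). Secondary-structure
#' annotations present in the blocks (`struct_conf`, `struct_sheet_range`)
#' are applied via [assign_secondary_structure()].
#'
#' @param blocks list of [cif_block()] objects (from any codec).
#' @return a `molstruct`.
#' @export
build_structure <- function(blocks) {
  if (inherits(blocks, "cif_block")) blocks <- list(blocks)
  b <- blocks[[1L]]
  as <- b$categories[["atom_site"]]
  if (is.null(as)) stop("no atom_site category in first block")
  nr <- cif_nrows(as)
  x <- column_num(as, "Cartn_x", nr)
  y <- column_num(as, "Cartn_y", nr)
  z <- column_num(as, "Cartn_z", nr)
  if (anyNA(x) || anyNA(y) || anyNA(z))
    stop("atom_site is missing Cartn_x/Cartn_y/Cartn_z coordinates")
  model <- column_num(as, "pdbx_PDB_model_num", nr)
  if (all(is.na(model))) model <- rep(1, nr)
  name <- column_chr(as, "label_atom_id", nr)
  if (all(is.na(name))) name <- column_chr(as, "auth_atom_id", nr)
  elem <- column_chr(as, "type_symbol", nr)
  elem <- ifelse(is.na(elem) | !nzchar(elem), infer_element(name), toupper(elem))
  comp <- column_chr(as, "label_comp_id", nr)
  if (all(is.na(comp))) comp <- column_chr(as, "auth_comp_id", nr)
  asym <- column_chr(as, "label_asym_id", nr)
  auth_asym <- column_chr(as, "auth_asym_id", nr)
  auth_asym[is.na(auth_asym)] <- asym[is.na(auth_asym)]
  asym[is.na(asym)] <- "A"
  seq_id <- column_num(as, "auth_seq_id", nr)
  lab_seq <- column_num(as, "label_seq_id", nr)
  seq_id[is.na(seq_id)] <- lab_seq[is.na(seq_id)]
  seq_id[is.na(seq_id)] <- 1
  ins <- column_chr(as, "pdbx_PDB_ins_code", nr)
  ins[is.na(ins)] <- ""
  group <- column_chr(as, "group_PDB", nr)
  hetero <- !is.na(group) & group == "HETATM"
  alt <- column_chr(as, "label_alt_id", nr)
  alt[is.na(alt)] <- ""
  occ <- column_num(as, "occupancy", nr); occ[is.na(occ)] <- 1
  bf <- column_num(as, "B_iso_or_equiv", nr); bf[is.na(bf)] <- 0
  serial <- column_num(as, "id", nr)
  if (anyNA(serial)) serial <- seq_len(nr)

  atoms_all <- data.frame(serial = as.integer(serial), name = name,
                          element = elem, alt_loc = alt, is_hetero = hetero,
                          comp_id = comp, seq_id = as.integer(seq_id),
                          ins_code = ins, asym_id = asym,
                          auth_asym_id = auth_asym, occupancy = occ,
                          b_factor = bf, stringsAsFactors = FALSE)
  models <- sort(unique(model))
  first_rows <- which(model == models[[1L]])
  topo <- atoms_all[first_rows, , drop = FALSE]
  keep <- altloc_filter(topo)
  topo <- topo[keep, , drop = FALSE]
  rownames(topo) <- NULL
  coords <- lapply(models, function(mn) {
    rows <- which(model == mn)
    if (length(rows) != length(first_rows))
      stop(sprintf("model %g has %d atoms, expected %d", mn,
                   length(rows), length(first_rows)))
    cbind(x[rows], y[rows], z[rows])[keep, , drop = FALSE]
  })
  st <- new_structure(topo, coords, entry_id = b$name)
  assign_secondary_structure(st, blocks)
}

# Keep-highest-occupancy alternate-location policy; returns logical keep mask.
altloc_filter <- function(atoms) {
  n <- nrow(atoms)
  keep <- rep(TRUE, n)
  has_alt <- nzchar(atoms$alt_loc) & atoms$alt_loc != "."
  if (!any(has_alt)) return(keep)
  key <- paste(atoms$asym_id, atoms$seq_id, atoms$ins_code, atoms$comp_id,
               atoms$name, sep = "\r")
  for (grp in split(which(has_alt), key[has_alt])) {
    if (length(grp) == 1L) next
    ord <- order(-atoms$occupancy[grp], atoms$alt_loc[grp])
    keep[grp[ord[-1L]]] <- FALSE
  }
  keep
}

# --- secondary structure ---------------------------------------------------

#' Assign secondary structure to polypeptide residues
#'
#' When `struct_conf` / `struct_sheet_range` categories (or ranges parsed
#' from PDB HELIX/SHEET records) are available they take precedence; residues
#' inside the listed ranges become helix/sheet. Otherwise a backbone-dihedral
#' heuristic is applied: a residue is helix when phi is in (-100, -30) and
#' psi in (-80, -5) degrees for itself and both neighbours, sheet when phi
#' is in (-180, -80) and psi in (80, 180) or (-180, -170) likewise, else
#' coil. The operation is idempotent.
#'
#' @param structure a `molstruct`.
#' @param blocks optional list of [cif_block()] carrying annotation
#'   categories, or a data.frame of ranges with columns `kind`
#'   (`"helix"`/`"sheet"`), `asym_id`, `beg`, `end` (author numbering).
#' @return the structure with `residues$ss` filled.
#' @export
assign_secondary_structure <- function(structure, blocks = NULL) {
  ranges <- ss_ranges_from(blocks)
  structure$residues$ss <- "coil"
  if (!is.null(ranges) && nrow(ranges)) {
    res <- structure$residues
    for (i in seq_len(nrow(ranges))) {
      hit <- (res$asym_id == ranges$asym_id[i] |
              res$auth_asym_id == ranges$asym_id[i]) &
             res$seq_id >= ranges$beg[i] & res$seq_id <= ranges$end[i]
      structure$residues$ss[hit] <- ranges$kind[i]
    }
    return(structure)
  }
  # dihedral heuristic, per polypeptide chain
  for (ci in seq_len(nrow(structure$chains))) {
    if (structure$chains$moltype[ci] != "polypeptide") next
    rix <- which(structure$residues$chain_index == ci)
    if (length(rix) < 3L) next
    tor <- backbone_dihedrals(structure, rix)
    phi <- tor$phi; psi <- tor$psi
    hel <- !is.na(phi) & !is.na(psi) &
      phi > -100 & phi < -30 & psi > -80 & psi < -5
    sht <- !is.na(phi) & !is.na(psi) &
      phi > -180 & phi < -80 &
      ((psi > 80 & psi <= 180) | (psi >= -180 & psi < -170))
    win <- function(v) v & c(v[-1L], FALSE) & c(FALSE, v[-length(v)])
    ss <- rep("coil", length(rix))
    ss[win(hel)] <- "helix"
    ss[win(sht)] <- "sheet"
    structure$residues$ss[rix] <- ss
  }
  structure
}

ss_ranges_from <- function(blocks) {
  if (is.null(blocks)) return(NULL)
  if (is.data.frame(blocks)) return(blocks)
  if (inherits(blocks, "cif_block")) blocks <- list(blocks)
  b <- blocks[[1L]]
  out <- list()
  sc <- b$categories[["struct_conf"]]
  if (!is.null(sc)) {
    nr <- cif_nrows(sc)
    conf <- column_chr(sc, "conf_type_id", nr)
    kind <- ifelse(!is.na(conf) & grepl("^STRN", conf), "sheet", "helix")
    out[[length(out) + 1L]] <- data.frame(
      kind = kind,
      asym_id = column_chr(sc, "beg_label_asym_id", nr),
      beg = range_seq(sc, "beg", nr), end = range_seq(sc, "end", nr),
      stringsAsFactors = FALSE)
  }
  sr <- b$categories[["struct_sheet_range"]]
  if (!is.null(sr)) {
    nr <- cif_nrows(sr)
    out[[length(out) + 1L]] <- data.frame(
      kind = "sheet",
      asym_id = column_chr(sr, "beg_label_asym_id", nr),
      beg = range_seq(sr, "beg", nr), end = range_seq(sr, "end", nr),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

range_seq <- function(cat, side, nr) {
  v <- column_num(cat, paste0(side, "_auth_seq_id"), nr)
  v2 <- column_num(cat, paste0(side, "_label_seq_id"), nr)
  v[is.na(v)] <- v2[is.na(v)]
  v
}

# phi/psi/omega (degrees) for the residues rix (a contiguous chain run).
backbone_dihedrals <- function(structure, rix, model = 1L) {
  co <- structure$coords[[model]]
  at <- structure$atoms
  pick <- function(ri, nm) {
    k <- which(at$residue_index == ri & at$name == nm)
    if (length(k)) k[[1L]] else NA_integer_
  }
  Nn <- vapply(rix, pick, 0L, nm = "N")
  CA <- vapply(rix, pick, 0L, nm = "CA")
  Cc <- vapply(rix, pick, 0L, nm = "C")
  m <- length(rix)
  phi <- psi <- omega <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    if (i > 1L && !anyNA(c(Cc[i - 1L], Nn[i], CA[i], Cc[i])))
      phi[i] <- dihedral_angle(co[Cc[i - 1L], ], co[Nn[i], ],
                               co[CA[i], ], co[Cc[i], ])
    if (i < m && !anyNA(c(Nn[i], CA[i], Cc[i], Nn[i + 1L])))
      psi[i] <- dihedral_angle(co[Nn[i], ], co[CA[i], ],
                               co[Cc[i], ], co[Nn[i + 1L], ])
    if (i > 1L && !anyNA(c(CA[i - 1L], Cc[i - 1L], Nn[i], CA[i])))
      omega[i] <- dihedral_angle(co[CA[i - 1L], ], co[Cc[i - 1L], ],
                                 co[Nn[i], ], co[CA[i], ])
  }
  list(phi = phi, psi = psi, omega = omega)
}

#' Dihedral angle of four points
#' @param p1,p2,p3,p4 numeric 3-vectors.
#' @return signed angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# --- bond inference --------------------------------------------------------

#' Infer covalent bonds from interatomic distances
#'
#' Atoms i and j are bonded when their distance lies in
#' `(0.4, r_i + r_j + 0.45]` Angstrom with `r` the single-bond covalent
#' radius. The pair search uses a 3-D cell grid (cell edge = maximum cutoff)
#' so cost grows near-linearly with atom count. Bonds across residues are
#' kept only between adjacent residues of one chain, plus disulphide-like
#' S-S pairs up to 2.5 Angstrom.
#'
#' @param structure a `molstruct`.
#' @param model model index used for distances.
#' @return 2-column integer matrix of 1-based atom index pairs (i < j).
#' @export
infer_bonds <- function(structure, model = 1L) {
  co <- structure$coords[[model]]
  n <- nrow(co)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  rad <- covalent_radius(structure$atoms$element)
  cutmax <- max(2 * max(rad) + BOND_TOL, 2.5)
  cell <- cutmax
  key <- floor(sweep(co, 2L, apply(co, 2L, min)) / cell)
  kid <- key[, 1L] + 4096 * (key[, 2L] + 4096 * key[, 3L])
  buckets <- split(seq_len(n), kid)
  bucket_of <- match(kid, as.numeric(names(buckets)))
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  pairs_i <- integer(0); pairs_j <- integer(0)
  seen_key <- function(k1, k2, k3) {
    paste(k1, k2, k3, sep = ",")
  }
  bucket_map <- new.env(parent = emptyenv())
  for (bi in seq_along(buckets)) {
    i0 <- buckets[[bi]][[1L]]
    assign(seen_key(key[i0, 1L], key[i0, 2L], key[i0, 3L]), buckets[[bi]],
           envir = bucket_map)
  }
  for (bi in seq_along(buckets)) {
    ii <- buckets[[bi]]
    k0 <- key[ii[[1L]], ]
    neigh <- integer(0)
    for (r in seq_len(nrow(offsets))) {
      kk <- k0 + offsets[r, ]
      hit <- bucket_map[[seen_key(kk[1L], kk[2L], kk[3L])]]
      if (!is.null(hit)) neigh <- c(neigh, hit)
    }
    for (a in ii) {
      cand <- neigh[neigh > a]
      if (!length(cand)) next
      d2 <- (co[cand, 1L] - co[a, 1L])^2 + (co[cand, 2L] - co[a, 2L])^2 +
            (co[cand, 3L] - co[a, 3L])^2
      cut <- (rad[a] + rad[cand] + BOND_TOL)^2
      ok <- d2 <= cut & d2 > BOND_MIN^2
      if (any(ok)) {
        pairs_i <- c(pairs_i, rep.int(a, sum(ok)))
        pairs_j <- c(pairs_j, cand[ok])
      }
    }
  }
  if (!length(pairs_i)) return(matrix(integer(0), ncol = 2L))
  bonds <- cbind(pairs_i, pairs_j)
  # inter-residue policy
  at <- structure$atoms
  ri <- at$residue_index[bonds[, 1L]]; rj <- at$residue_index[bonds[, 2L]]
  ci <- structure$residues$chain_index[ri]
  cj <- structure$residues$chain_index[rj]
  same_res <- ri == rj
  adjacent <- ci == cj & abs(ri - rj) == 1L
  co1 <- co[bonds[, 1L], , drop = FALSE]; co2 <- co[bonds[, 2L], , drop = FALSE]
  dist <- sqrt(rowSums((co1 - co2)^2))
  ss_pair <- at$element[bonds[, 1L]] == "S" & at$element[bonds[, 2L]] == "S" &
    dist <= 2.5
  keep <- same_res | adjacent | ss_pair
  bonds <- bonds[keep, , drop = FALSE]
  dimnames(bonds) <- NULL
  bonds[order(bonds[, 1L], bonds[, 2L]), , drop = FALSE]
}

# Brute-force O(n^2) bond finder: the oracle for the grid method.
infer_bonds_brute <- function(structure, model = 1L) {
  co <- structure$coords[[model]]
  n <- nrow(co)
  rad <- covalent_radius(structure$atoms$element)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- sqrt(rowSums((co[pairs[, 1L], , drop = FALSE] -
                     co[pairs[, 2L], , drop = FALSE])^2))
  ok <- d <= rad[pairs[, 1L]] + rad[pairs[, 2L]] + BOND_TOL & d > BOND_MIN
  bonds <- pairs[ok, , drop = FALSE]
  at <- structure$atoms
  ri <- at$residue_index[bonds[, 1L]]; rj <- at$residue_index[bonds[, 2L]]
  ci <- structure$residues$chain_index[ri]
  cj <- structure$residues$chain_index[rj]
  dist <- d[ok]
  keep <- ri == rj | (ci == cj & abs(ri - rj) == 1L) |
    (at$element[bonds[, 1L]] == "S" & at$element[bonds[, 2L]] == "S" &
       dist <= 2.5)
  bonds <- bonds[keep, , drop = FALSE]
  dimnames(bonds) <- NULL
  bonds[order(bonds[, 1L], bonds[, 2L]), , drop = FALSE]
}

#' Bonds for a structure, preferring explicit file bonds
#' @param structure a `molstruct`.
#' @return 2-column integer matrix.
#' @export
structure_bonds <- function(structure) {
  if (!is.null(structure$bonds) && nrow(structure$bonds)) return(structure$bonds)
  infer_bonds(structure)
}

#' Centroid and bounding radius of a selection
#'
#' @param structure a `molstruct`.
#' @param sel a selection from [select_atoms()] (or integer atom indices).
#' @param model model index.
#' @return list with `center` (3-vector) and `radius` (max distance from the
#'   centroid to any selected atom).
#' @export
focus_target <- function(structure, sel, model = 1L) {
  idx <- as_atom_indices(structure, sel)
  if (!length(idx)) stop("empty selection: nothing to focus on")
  co <- structure$coords[[model]][idx, , drop = FALSE]
  center <- colMeans(co)
  radius <- if (nrow(co) == 1L) 0 else
    sqrt(max(rowSums(sweep(co, 2L, center)^2)))
  list(center = center, radius = radius)
}
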