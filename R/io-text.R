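#' Parse a legacy PDB flat file
#'
#' Fixed-column ATOM/HETATM parsing at the standard offsets (serial 7-11,
#' name 13-16, altLoc 17, resName 18-20, chain 22, resSeq 23-26, iCode 27,
#' coordinates 31-54, occupancy 55-60, tempFactor 61-66, element 77-78).
#' MODEL/ENDMDL delimit models (all must have the same atom count), TER ends
#' a chain, and HELIX/SHEET records feed the secondary-structure annotation.
#' Alternate locations are reduced by the highest-occupancy policy.
#'
#' @param text PDB document (string or character vector of lines).
#' @param path alternatively a file path (gzip detected by magic bytes).
#' @param entry_id entry identifier (default from HEADER, else "").
#' @return a `molstruct`.
#' @export
parse_pdb <- function(text = NULL, path = NULL, entry_id = NULL) {
  if (is.null(text)) text <- read_text_auto(path)
  lines <- if (length(text) > 1L) text else strsplit(text, "\n", fixed = TRUE)[[1L]]
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  f <- function(l, a, b) substr(l, a, b)
  num <- function(s, what, ln) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v) & nzchar(trimws(s)))
    if (length(bad))
      stop(sprintf("line %d: non-numeric %s field '%s'",
                   ln[bad[[1L]]], what, s[bad[[1L]]]))
    v
  }
  # model bookkeeping + TER-based chain splitting
  model_no <- integer(0); ter_seg <- integer(0)
  cur_model <- 1L; seg <- 0L
  midx <- integer(length(lines)); tseg <- integer(length(lines))
  seen_model_rec <- FALSE
  for (i in seq_along(lines)) {
    r <- rec[[i]]
    if (r == "MODEL ") {
      v <- suppressWarnings(as.integer(trimws(substr(lines[[i]], 7L, 80L))))
      cur_model <- if (is.na(v)) cur_model + 1L else v
      seen_model_rec <- TRUE
      seg <- 0L
    } else if (r == "ENDMDL") {
      seg <- 0L
    } else if (r == "TER   " || trimws(r) == "TER") {
      seg <- seg + 1L
    }
    midx[[i]] <- cur_model
    tseg[[i]] <- seg
  }
  al <- which(is_atom)
  if (!length(al)) stop("no ATOM/HETATM records found")
  L <- lines[al]
  ln <- al
  x <- num(f(L, 31L, 38L), "x", ln)
  y <- num(f(L, 39L, 46L), "y", ln)
  z <- num(f(L, 47L, 54L), "z", ln)
  if (anyNA(x) || anyNA(y) || anyNA(z))
    stop(sprintf("line %d: missing coordinate", ln[which(is.na(x + y + z))[1L]]))
  occ <- num(f(L, 55L, 60L), "occupancy", ln); occ[is.na(occ)] <- 1
  bf <- num(f(L, 61L, 66L), "tempFactor", ln); bf[is.na(bf)] <- 0
  serial <- suppressWarnings(as.integer(trimws(f(L, 7L, 11L))))
  serial[is.na(serial)] <- seq_along(serial)[is.na(serial)]
  name <- trimws(f(L, 13L, 16L))
  alt <- trimws(f(L, 17L, 17L))
  resn <- trimws(f(L, 18L, 20L))
  chain <- trimws(f(L, 22L, 22L))
  resseq <- suppressWarnings(as.integer(trimws(f(L, 23L, 26L))))
  resseq[is.na(resseq)] <- 0L
  icode <- trimws(f(L, 27L, 27L))
  elem <- toupper(trimws(f(L, 77L, 78L)))
  elem <- ifelse(nzchar(elem), elem, infer_element(name))
  het <- rec[al] == "HETATM"
  model <- midx[al]
  # chain id: author letter plus TER segmentation for blank-chain files
  asym <- ifelse(nzchar(chain), chain, paste0("SEG", tseg[al] + 1L))
  atoms_all <- data.frame(serial = serial, name = name, element = elem,
                          alt_loc = alt, is_hetero = het, comp_id = resn,
                          seq_id = resseq, ins_code = icode, asym_id = asym,
                          auth_asym_id = ifelse(nzchar(chain), chain, asym),
                          occupancy = occ, b_factor = bf,
                          stringsAsFactors = FALSE)
  models <- sort(unique(model))
  rows1 <- which(model == models[[1L]])
  topo <- atoms_all[rows1, , drop = FALSE]
  keep <- altloc_filter(topo)
  topo <- topo[keep, , drop = FALSE]
  rownames(topo) <- NULL
  coords <- lapply(models, function(mn) {
    rows <- which(model == mn)
    if (length(rows) != length(rows1))
      stop(sprintf("model %d has %d atoms, expected %d", mn, length(rows),
                   length(rows1)))
    cbind(x[rows], y[rows], z[rows])[keep, , drop = FALSE]
  })
  if (is.null(entry_id)) {
    hd <- lines[rec == "HEADER"]
    entry_id <- if (length(hd)) trimws(substr(hd[[1L]], 63L, 66L)) else ""
  }
  st <- new_structure(topo, coords, entry_id = entry_id)
  # HELIX (chain 20, init 22-25, end 34-37); SHEET (chain 22, init 23-26, end 34-37)
  ranges <- list()
  for (l in lines[rec == "HELIX "])
    ranges[[length(ranges) + 1L]] <- data.frame(
      kind = "helix", asym_id = trimws(substr(l, 20L, 20L)),
      beg = as.integer(trimws(substr(l, 22L, 25L))),
      end = as.integer(trimws(substr(l, 34L, 37L))),
      stringsAsFactors = FALSE)
  for (l in lines[rec == "SHEET "])
    ranges[[length(ranges) + 1L]] <- data.frame(
      kind = "sheet", asym_id = trimws(substr(l, 22L, 22L)),
      beg = as.integer(trimws(substr(l, 23L, 26L))),
      end = as.integer(trimws(substr(l, 34L, 37L))),
      stringsAsFactors = FALSE)
  ranges <- if (length(ranges)) do.call(rbind, ranges) else NULL
  assign_secondary_structure(st, ranges)
}

#' Parse a Gromacs GRO file
#'
#' Fixed columns: residue number 1-5, residue name 6-10, atom name 11-15,
#' atom number 16-20, x/y/z in nm at 21-44 (converted to Angstrom). The
#' trailing box line is parsed into box vectors (Angstrom); optional
#' velocity columns are ignored.
#'
#' @param text GRO document string or lines.
#' @param path alternatively a file path.
#' @return a `molstruct` with attribute `box` (3x3 matrix, Angstrom).
#' @export
parse_gro <- function(text = NULL, path = NULL) {
  if (is.null(text)) text <- read_text_auto(path)
  lines <- if (length(text) > 1L) text else strsplit(text, "\n", fixed = TRUE)[[1L]]
  lines <- lines[nzchar(lines) | seq_along(lines) <= 2L]
  if (length(lines) < 3L) stop("GRO file too short")
  title <- lines[[1L]]
  nat <- suppressWarnings(as.integer(trimws(lines[[2L]])))
  if (is.na(nat)) stop("GRO atom-count line is not an integer")
  if (length(lines) < nat + 3L)
    stop(sprintf("GRO file declares %d atoms but has %d atom lines (missing box line?)",
                 nat, max(0L, length(lines) - 3L)))
  al <- lines[3:(2L + nat)]
  resid <- as.integer(trimws(substr(al, 1L, 5L)))
  resn <- trimws(substr(al, 6L, 10L))
  name <- trimws(substr(al, 11L, 15L))
  serial <- suppressWarnings(as.integer(trimws(substr(al, 16L, 20L))))
  xyz <- function(a, b) {
    v <- suppressWarnings(as.numeric(trimws(substr(al, a, b))))
    if (anyNA(v)) stop("non-numeric GRO coordinate")
    v * 10  # nm -> Angstrom
  }
  x <- xyz(21L, 28L); y <- xyz(29L, 36L); z <- xyz(37L, 44L)
  boxline <- trimws(lines[[3L + nat]])
  if (!nzchar(boxline)) stop("GRO file is missing its box line")
  bv <- suppressWarnings(as.numeric(strsplit(boxline, "[ \t]+")[[1L]]))
  if (anyNA(bv) || !length(bv) %in% c(3L, 9L))
    stop("GRO box line must have 3 or 9 numeric fields")
  box <- matrix(0, 3L, 3L)
  if (length(bv) == 3L) diag(box) <- bv * 10
  else {
    box[1, 1] <- bv[1]; box[2, 2] <- bv[2]; box[3, 3] <- bv[3]
    box[1, 2] <- bv[4]; box[1, 3] <- bv[5]; box[2, 1] <- bv[6]
    box[2, 3] <- bv[7]; box[3, 1] <- bv[8]; box[3, 2] <- bv[9]
    box <- box * 10
  }
  atoms <- data.frame(serial = ifelse(is.na(serial), seq_len(nat), serial),
                      name = name, element = infer_element(name),
                      alt_loc = "", is_hetero = FALSE, comp_id = resn,
                      seq_id = resid, ins_code = "", asym_id = "A",
                      auth_asym_id = "A", occupancy = 1, b_factor = 0,
                      stringsAsFactors = FALSE)
  co <- cbind(x, y, z)
  dimnames(co) <- NULL
  st <- new_structure(atoms, list(co), entry_id = trimws(title))
  attr(st, "box") <- box
  st
}

#' Parse a TRIPOS MOL2 file
#'
#' Reads the `@<TRIPOS>MOLECULE`, `ATOM` and `BOND` sections; SYBYL atom
#' types (e.g. `C.3`, `N.ar`) are reduced to elements; the explicit bond
#' list is stored on the structure and overrides distance-based inference.
#'
#' @param text MOL2 document string or lines.
#' @param path alternatively a file path.
#' @return a `molstruct`.
#' @export
parse_mol2 <- function(text = NULL, path = NULL) {
  if (is.null(text)) text <- read_text_auto(path)
  lines <- if (length(text) > 1L) text else strsplit(text, "\n", fixed = TRUE)[[1L]]
  sec <- which(startsWith(lines, "@<TRIPOS>"))
  if (!length(sec)) stop("not a MOL2 file: no @<TRIPOS> sections")
  secname <- sub("@<TRIPOS>", "", lines[sec], fixed = TRUE)
  get_sec <- function(nm) {
    i <- sec[match(nm, secname)]
    if (is.na(i)) return(NULL)
    j <- sec[sec > i]
    end <- if (length(j)) min(j) - 1L else length(lines)
    body <- lines[(i + 1L):end]
    body[nzchar(trimws(body)) & !startsWith(body, "#")]
  }
  mol <- get_sec("MOLECULE")
  if (is.null(mol)) stop("MOL2 file is missing @<TRIPOS>MOLECULE")
  atom <- get_sec("ATOM")
  if (is.null(atom)) stop("MOL2 file is missing @<TRIPOS>ATOM")
  fields <- strsplit(trimws(atom), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 6L)) stop("MOL2 ATOM record with fewer than 6 fields")
  m <- function(k) vapply(fields, `[[`, "", k)
  sybyl <- m(6L)
  elem <- toupper(sub("\\..*$", "", sybyl))
  name <- m(2L)
  xyz <- cbind(as.numeric(m(3L)), as.numeric(m(4L)), as.numeric(m(5L)))
  resid <- if (all(nf >= 7L)) as.integer(m(7L)) else rep(1L, length(fields))
  resn <- if (all(nf >= 8L)) m(8L) else rep("LIG", length(fields))
  atoms <- data.frame(serial = as.integer(m(1L)), name = name, element = elem,
                      alt_loc = "", is_hetero = TRUE, comp_id = resn,
                      seq_id = resid, ins_code = "", asym_id = "A",
                      auth_asym_id = "A", occupancy = 1, b_factor = 0,
                      stringsAsFactors = FALSE)
  bonds <- NULL
  bl <- get_sec("BOND")
  if (!is.null(bl) && length(bl)) {
    bf <- strsplit(trimws(bl), "[ \t]+")
    bonds <- cbind(vapply(bf, function(v) as.integer(v[[2L]]), 0L),
                   vapply(bf, function(v) as.integer(v[[3L]]), 0L))
  }
  title <- trimws(mol[[1L]])
  new_structure(atoms, list(xyz), entry_id = title, bonds = bonds)
}

#' Parse an MDL MOL / SDF (V2000) record
#'
#' Reads the first connection-table of the document: the counts line (atoms
#' in columns 1-3, bonds in 4-6), the atom block (x, y, z, element) and the
#' bond block. Explicit bonds are stored on the structure.
#'
#' @param text MDL document string or lines.
#' @param path alternatively a file path.
#' @return a `molstruct`.
#' @export
parse_mdl <- function(text = NULL, path = NULL) {
  if (is.null(text)) text <- read_text_auto(path)
  lines <- if (length(text) > 1L) text else strsplit(text, "\n", fixed = TRUE)[[1L]]
  if (length(lines) < 4L) stop("MDL file too short for a counts line")
  counts <- lines[[4L]]
  na <- suppressWarnings(as.integer(trimws(substr(counts, 1L, 3L))))
  nb <- suppressWarnings(as.integer(trimws(substr(counts, 4L, 6L))))
  if (is.na(na) || is.na(nb)) stop("MDL counts line is malformed")
  if (length(lines) < 4L + na + nb) stop("MDL file truncated before block end")
  al <- lines[5:(4L + na)]
  x <- as.numeric(substr(al, 1L, 10L))
  y <- as.numeric(substr(al, 11L, 20L))
  z <- as.numeric(substr(al, 21L, 30L))
  elem <- toupper(trimws(substr(al, 32L, 34L)))
  if (anyNA(x) || anyNA(y) || anyNA(z)) stop("non-numeric MDL coordinate")
  bonds <- NULL
  if (nb > 0L) {
    bl <- lines[(5L + na):(4L + na + nb)]
    bonds <- cbind(as.integer(trimws(substr(bl, 1L, 3L))),
                   as.integer(trimws(substr(bl, 4L, 6L))))
  }
  atoms <- data.frame(serial = seq_len(na),
                      name = paste0(elem, seq_len(na)), element = elem,
                      alt_loc = "", is_hetero = TRUE, comp_id = "LIG",
                      seq_id = 1L, ins_code = "", asym_id = "A",
                      auth_asym_id = "A", occupancy = 1, b_factor = 0,
                      stringsAsFactors = FALSE)
  co <- cbind(x, y, z)
  dimnames(co) <- NULL
  new_structure(atoms, list(co),
                entry_id = trimws(lines[[1L]]), bonds = bonds)
}
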