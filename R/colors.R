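#' @title Colour schemes
#' @description
#' Per-atom and per-residue colour assignment: CPK element colours, the
#' blue-to-red group gradient, a cycled chain palette, secondary-structure
#' colours, ABEGO backbone-conformation classes and custom overrides. All
#' colours are RGBA integer vectors in 0-255. Palettes are fixed constants
#' so rendered images are reproducible across releases.
#' @name color-schemes
NULL

# CPK element palette; unknown elements get the fallback pink.
CPK_TABLE <- rbind(
  C = c(200L, 200L, 200L), N = c(0L, 0L, 255L), O = c(255L, 0L, 0L),
  S = c(255L, 200L, 50L), H = c(255L, 255L, 255L), P = c(255L, 165L, 0L))
CPK_FALLBACK <- c(255L, 20L, 147L)

#' CPK colour of an element
#' @param element element symbol (case-insensitive); vectorized.
#' @return RGBA matrix (one row per element) or a single RGBA vector.
#' @export
cpk_color <- function(element) {
  key <- toupper(element)
  out <- t(vapply(key, function(k) {
    if (k %in% rownames(CPK_TABLE)) CPK_TABLE[k, ] else CPK_FALLBACK
  }, integer(3)))
  out <- cbind(out, 255L)
  rownames(out) <- NULL
  if (length(element) == 1L) out[1L, ] else out
}

#' Blue-to-red group gradient
#'
#' Hue interpolated linearly from 240 degrees (blue) to 0 (red) in HSV with
#' full saturation and value; a single group is blue.
#'
#' @param index 0-based group index.
#' @param n number of groups (>= 1).
#' @return RGBA integer vector.
#' @export
group_gradient <- function(index, n) {
  stopifnot(n >= 1)
  if (index < 0 || index > n - 1) stop("group index out of range")
  hue <- if (n == 1L) 240 else 240 * (1 - index / (n - 1))
  c(hsv_to_rgb(hue, 1, 1), 255L)
}

hsv_to_rgb <- function(h, s, v) {
  rgb <- grDevices::col2rgb(grDevices::hsv(h / 360, s, v))
  as.integer(rgb[, 1L])
}

CHAIN_PALETTE <- rbind(
  c(102L, 153L, 255L), c(255L, 153L, 102L), c(153L, 255L, 102L),
  c(255L, 102L, 204L), c(102L, 255L, 255L), c(255L, 255L, 102L),
  c(204L, 102L, 255L), c(255L, 102L, 102L), c(102L, 255L, 153L),
  c(153L, 153L, 255L), c(255L, 204L, 102L), c(102L, 204L, 153L))

#' Chain colour (12-colour palette, cycled)
#' @param chain_index 0-based chain index.
#' @return RGBA integer vector.
#' @export
chain_color <- function(chain_index) {
  c(CHAIN_PALETTE[(chain_index %% 12L) + 1L, ], 255L)
}

SS_COLORS <- list(helix = c(255L, 0L, 128L, 255L),
                  sheet = c(255L, 200L, 0L, 255L),
                  coil = c(200L, 200L, 200L, 255L))

#' Secondary-structure colour
#' @param ss one of `"helix"`, `"sheet"`, `"coil"` (anything else is coil).
#' @return RGBA integer vector.
#' @export
ss_color <- function(ss) {
  hit <- SS_COLORS[[ss]]
  if (is.null(hit)) SS_COLORS$coil else hit
}

ABEGO_COLORS <- list(A = c(255L, 60L, 60L, 255L),  # alpha region
                     B = c(60L, 60L, 255L, 255L),  # beta region
                     E = c(60L, 200L, 255L, 255L), # left beta
                     G = c(60L, 220L, 60L, 255L),  # left helical
                     O = c(255L, 200L, 0L, 255L),  # cis peptide
                     "-" = c(150L, 150L, 150L, 255L))

#' ABEGO class of a backbone conformation
#'
#' Classifies a residue by its backbone dihedrals: `O` for cis peptides
#' (|omega| < 90 degrees); otherwise, for phi < 0, `A` (helical) when
#' -75 <= psi < 50 and `B` (extended) otherwise; for phi >= 0, `G`
#' (left-handed helical) when -100 <= psi < 100 and `E` otherwise.
#' Undefined dihedrals (chain termini) give `"-"`.
#'
#' @param phi,psi,omega backbone dihedrals in degrees, in `[-180, 180]`.
#' @return single character label in `{"A","B","E","G","O","-"}`.
#' @export
abego_class <- function(phi, psi, omega = 180) {
  if (anyNA(c(phi, psi, omega))) return("-")
  stopifnot(abs(phi) <= 180, abs(psi) <= 180, abs(omega) <= 180)
  if (abs(omega) < 90) return("O")
  if (phi < 0) {
    if (psi >= -75 && psi < 50) "A" else "B"
  } else {
    if (psi >= -100 && psi < 100) "G" else "E"
  }
}

#' Apply a colouring scheme to a structure
#'
#' Evaluates the base scheme per atom (residue-level schemes broadcast to
#' their atoms), then applies overrides in order, last wins.
#'
#' @param structure a `molstruct`.
#' @param selection atoms to colour (`NULL` = all); atoms outside the
#'   selection still receive a row (the base grey) so the output always has
#'   one row per atom.
#' @param scheme one of `"cpk"`, `"group"`, `"chain"`, `"ss"`, `"abego"`,
#'   `"custom"`.
#' @param overrides named list mapping selection expressions to colours
#'   (RGBA vector, hex string `"#rrggbb"` or a CSS/R colour name); required
#'   for `scheme = "custom"`.
#' @return `n_atoms x 4` integer RGBA matrix.
#' @export
apply_scheme <- function(structure, selection = NULL, scheme = "cpk",
                         overrides = NULL) {
  scheme <- match.arg(scheme, c("cpk", "group", "chain", "ss", "abego",
                                "custom"))
  if (scheme == "custom" && is.null(overrides))
    stop("custom scheme requires overrides")
  n <- n_atoms(structure)
  at <- structure$atoms
  res <- structure$residues
  cols <- matrix(rep(GREY, each = n), n, 4L)
  idx <- as_atom_indices(structure, selection)
  if (scheme == "cpk") {
    cols[idx, ] <- cpk_color(at$element[idx])
  } else if (scheme == "chain") {
    ci <- res$chain_index[at$residue_index[idx]]
    cols[idx, ] <- t(vapply(ci - 1L, chain_color, integer(4)))
  } else if (scheme == "ss") {
    ss <- res$ss[at$residue_index[idx]]
    cols[idx, ] <- t(vapply(ss, function(s) ss_color(s), integer(4)))
  } else if (scheme == "group") {
    ri <- at$residue_index[idx]
    ci <- res$chain_index[ri]
    for (ch in unique(ci)) {
      rr <- which(res$chain_index == ch)
      nr <- length(rr)
      sub <- idx[ci == ch]
      gi <- match(at$residue_index[sub], rr) - 1L
      cols[sub, ] <- t(vapply(gi, function(g) group_gradient(g, nr),
                              integer(4)))
    }
  } else if (scheme == "abego") {
    for (ci in seq_len(nrow(structure$chains))) {
      rix <- which(res$chain_index == ci)
      labs <- rep("-", length(rix))
      if (structure$chains$moltype[ci] == "polypeptide" && length(rix) >= 2L) {
        tor <- backbone_dihedrals(structure, rix)
        labs <- vapply(seq_along(rix), function(q)
          abego_class(tor$phi[q], tor$psi[q],
                      if (is.na(tor$omega[q])) 180 else tor$omega[q]), "")
      }
      for (q in seq_along(rix)) {
        sub <- idx[at$residue_index[idx] == rix[q]]
        if (length(sub))
          cols[sub, ] <- matrix(rep(ABEGO_COLORS[[labs[q]]], each = length(sub)),
                                length(sub), 4L)
      }
    }
  }
  for (nm in names(overrides)) {
    oc <- parse_color(overrides[[nm]])
    sub <- as_atom_indices(structure, nm)
    sub <- intersect(sub, idx)
    if (length(sub))
      cols[sub, ] <- matrix(rep(oc, each = length(sub)), length(sub), 4L)
  }
  storage.mode(cols) <- "integer"
  cols
}

#' Parse a colour specification to RGBA
#' @param x RGBA integer vector, hex string (`"#rrggbb"`/`"#rrggbbaa"`) or a
#'   colour name known to R/CSS.
#' @return RGBA integer vector.
#' @export
parse_color <- function(x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (length(x) == 3L) x <- c(x, 255L)
    if (length(x) != 4L || any(x < 0L | x > 255L)) stop("bad RGBA colour")
    return(x)
  }
  rgba <- tryCatch(grDevices::col2rgb(x, alpha = TRUE)[, 1L],
                   error = function(e) stop(sprintf("unknown colour '%s'", x)))
  as.integer(rgba)
}
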