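#' @title STAR data model: blocks, categories, columns, cells
#'
#' @description
#' The in-memory data model shared by the mmCIF, PDBML and mmJSON codecs.
#' A *block* is a named, ordered collection of *categories*; a category is an
#' ordered map of item keywords to equal-length *columns*; a cell is a tagged
#' value: integer, real, text, or null. Null encodes both the mmCIF "?"
#' (unknown) and "." (inapplicable) tokens; the distinction is not preserved
#' (both re-serialize as "?").
#'
#' Cells are stored as R values: `NULL` (null), `integer` or whole `double`
#' (integer cell), `double` (real cell), `character` (text cell).
#' @name star-model
NULL

#' Construct a data block
#'
#' @param name block identifier (the text after `data_`); must be non-empty.
#' @param categories named list of categories created by [cif_category()].
#' @return an object of class `cif_block`.
#' @export
cif_block <- function(name, categories = list()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("block name must be a non-empty string")
  nms <- vapply(categories, function(x) x$name, "")
  if (anyDuplicated(nms)) stop("duplicate category names in block")
  names(categories) <- nms
  structure(list(name = name, categories = categories), class = "cif_block")
}

#' Construct a category
#'
#' @param name category name without the leading underscore.
#' @param columns named list; each element is a list of cells (one per row).
#' @return an object of class `cif_category`.
#' @export
cif_category <- function(name, columns = list()) {
  if (!nzchar(name)) stop("category name must be non-empty")
  if (length(columns)) {
    if (is.null(names(columns)) || any(!nzchar(names(columns))))
      stop("all columns must be named")
    if (anyDuplicated(names(columns))) stop("duplicate item keywords")
    lens <- lengths(columns)
    if (length(unique(lens)) > 1L)
      stop(sprintf("ragged category '%s': column lengths %s", name,
                   paste(lens, collapse = ", ")))
    columns <- lapply(columns, as.list)
  }
  structure(list(name = name, columns = columns), class = "cif_category")
}

#' Number of rows in a category
#' @param cat a `cif_category`.
#' @return integer row count (0 for a column-less category).
#' @export
cif_nrows <- function(cat) {
  if (!length(cat$columns)) return(0L)
  length(cat$columns[[1L]])
}

#' @export
print.cif_block <- function(x, ...) {
  cat(sprintf("<cif_block> data_%s: %d categories\n", x$name,
              length(x$categories)))
  for (cc in x$categories)
    cat(sprintf("  %-30s %d cols x %d rows\n", cc$name,
                length(cc$columns), cif_nrows(cc)))
  invisible(x)
}

#' @export
print.cif_category <- function(x, ...) {
  cat(sprintf("<cif_category> %s: %d cols x %d rows\n", x$name,
              length(x$columns), cif_nrows(x)))
  invisible(x)
}

# Typed-value coercion for an unquoted STAR token.
# "?" and "." -> NULL; fully-numeric tokens -> integer/real; leading-zero
# padded integer tokens ("007") stay text so author identifiers survive.
star_typed_value <- function(token) {
  if (token == "?" || token == ".") return(NULL)
  if (grepl("^[+-]?[0-9]+$", token)) {
    if (grepl("^[+-]?0[0-9]", token)) return(token)  # zero-padded id
    v <- suppressWarnings(as.numeric(token))
    if (is.na(v)) return(token)
    if (abs(v) <= .Machine$integer.max) return(as.integer(v))
    return(v)  # big integer: whole double
  }
  if (grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", token) &&
      grepl("[.eE]", token)) {
    v <- suppressWarnings(as.numeric(token))
    if (!is.na(v)) return(v)
  }
  token
}

# Is this cell an integer cell? (whole doubles beyond int range count)
cell_is_integer <- function(x) {
  if (is.null(x)) return(FALSE)
  if (is.integer(x)) return(TRUE)
  is.numeric(x) && is.finite(x) && x == floor(x) && !inherits(x, "cif_real")
}

#' Compare two blocks (or block lists) for value identity
#'
#' Integer and real cells compare numerically (a real that happens to be
#' whole equals the same integer); reals compare to a relative tolerance;
#' nulls compare equal to nulls only.
#'
#' @param a,b `cif_block` objects or lists of them.
#' @param tol relative tolerance for real-valued cells.
#' @return `TRUE` or a character description of the first difference.
#' @export
cif_identical <- function(a, b, tol = 1e-12) {
  if (inherits(a, "cif_block")) a <- list(a)
  if (inherits(b, "cif_block")) b <- list(b)
  if (length(a) != length(b)) return("different number of blocks")
  for (i in seq_along(a)) {
    ba <- a[[i]]; bb <- b[[i]]
    if (ba$name != bb$name) return(sprintf("block name %s != %s", ba$name, bb$name))
    if (!identical(names(ba$categories), names(bb$categories)))
      return(sprintf("block %s: category sets differ", ba$name))
    for (cn in names(ba$categories)) {
      ca <- ba$categories[[cn]]; cb <- bb$categories[[cn]]
      if (!identical(names(ca$columns), names(cb$columns)))
        return(sprintf("category %s: item sets differ", cn))
      for (kn in names(ca$columns)) {
        va <- ca$columns[[kn]]; vb <- cb$columns[[kn]]
        if (length(va) != length(vb))
          return(sprintf("%s.%s: row counts differ", cn, kn))
        for (r in seq_along(va)) {
          x <- va[[r]]; y <- vb[[r]]
          if (is.null(x) || is.null(y)) {
            if (!(is.null(x) && is.null(y)))
              return(sprintf("%s.%s row %d: null mismatch", cn, kn, r))
          } else if (is.numeric(x) && is.numeric(y)) {
            d <- abs(as.numeric(x) - as.numeric(y))
            s <- max(abs(as.numeric(x)), abs(as.numeric(y)), 1)
            if (d > tol * s)
              return(sprintf("%s.%s row %d: %.17g != %.17g", cn, kn, r,
                             as.numeric(x), as.numeric(y)))
          } else if (!identical(as.character(x), as.character(y)) ||
                     is.numeric(x) != is.numeric(y)) {
            return(sprintf("%s.%s row %d: '%s' != '%s'", cn, kn, r,
                           paste(x), paste(y)))
          }
        }
      }
    }
  }
  TRUE
}

# Normalize a parsed raw/character input: transparently gunzip by magic bytes.
read_text_auto <- function(path) {
  con <- file(path, "rb")
  magic <- readBin(con, "raw", 2L)
  close(con)
  if (length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)) {
    con <- gzfile(path, "rb")
    on.exit(close(con))
    return(rawToChar(readBin(con, "raw", 100e6)))
  }
  readChar(path, file.size(path), useBytes = TRUE)
}
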