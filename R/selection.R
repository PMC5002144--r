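#' Select atoms with the selection mini-language
#'
#' Grammar (EBNF):
#' \preformatted{
#'   expr    = or_expr ;
#'   or_expr = and_expr , { "or" , and_expr } ;
#'   and_expr= unary , { "and" , unary } ;
#'   unary   = "not" , unary | primary ;
#'   primary = "(" , expr , ")" | term ;
#'   term    = "chain" , id | "resi" , int , [ "-" , int ]
#'           | "resn" , name | "name" , name | "hetero" | "polymer" ;
#' }
#' `chain` matches the author chain id (falling back to the label asym id),
#' `resi` uses inclusive author residue numbers, `hetero` selects HETATM-like
#' atoms and `polymer` selects non-hetero atoms of polypeptide or nucleic
#' chains.
#'
#' @param structure a `molstruct`.
#' @param expr selection expression string.
#' @return an object of class `molsel`: sorted integer atom indices with the
#'   source expression as an attribute.
#' @examples
#' # select_atoms(st, "chain A and resi 10-20 and not hetero")
#' @export
select_atoms <- function(structure, expr) {
  toks <- sel_tokenize(expr)
  st <- list(toks = toks, pos = 1L, src = expr)
  env <- new.env(parent = emptyenv())
  env$st <- st
  mask <- sel_parse_or(env, structure)
  if (env$st$pos <= length(env$st$toks$value))
    sel_err(env, "trailing input")
  idx <- which(mask)
  structure(idx, class = "molsel", expr = expr)
}

#' @export
print.molsel <- function(x, ...) {
  cat(sprintf("<molsel> %d atoms: %s\n", length(x),
              attr(x, "expr") %||% ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce a selection-ish thing (molsel, integer vector, expression string,
# NULL = everything) to atom indices.
as_atom_indices <- function(structure, sel) {
  if (is.null(sel)) return(seq_len(n_atoms(structure)))
  if (inherits(sel, "molsel")) return(as.integer(sel))
  if (is.character(sel)) return(as.integer(select_atoms(structure, sel)))
  idx <- as.integer(sel)
  if (length(idx) && (min(idx) < 1L || max(idx) > n_atoms(structure)))
    stop("atom indices out of range")
  idx
}

sel_tokenize <- function(expr) {
  vals <- character(0); pos <- integer(0)
  chars <- strsplit(expr, "", fixed = TRUE)[[1L]]
  n <- length(chars); i <- 1L
  while (i <= n) {
    c0 <- chars[[i]]
    if (c0 %in% c(" ", "\t")) { i <- i + 1L; next }
    if (c0 %in% c("(", ")")) {
      vals <- c(vals, c0); pos <- c(pos, i); i <- i + 1L; next
    }
    j <- i
    while (j <= n && !(chars[[j]] %in% c(" ", "\t", "(", ")"))) j <- j + 1L
    vals <- c(vals, paste(chars[i:(j - 1L)], collapse = ""))
    pos <- c(pos, i)
    i <- j
  }
  list(value = vals, pos = pos)
}

sel_err <- function(env, msg) {
  p <- env$st$pos
  at <- if (p <= length(env$st$toks$pos)) env$st$toks$pos[[p]]
        else nchar(env$st$src) + 1L
  stop(sprintf("selection syntax error at position %d ('%s'): %s",
               at, env$st$src, msg), call. = FALSE)
}

sel_peek <- function(env) {
  p <- env$st$pos
  if (p > length(env$st$toks$value)) NA_character_ else env$st$toks$value[[p]]
}

sel_next <- function(env) {
  v <- sel_peek(env)
  if (is.na(v)) sel_err(env, "unexpected end of expression")
  env$st$pos <- env$st$pos + 1L
  v
}

sel_parse_or <- function(env, structure) {
  m <- sel_parse_and(env, structure)
  while (!is.na(sel_peek(env)) && tolower(sel_peek(env)) == "or") {
    sel_next(env)
    m <- m | sel_parse_and(env, structure)
  }
  m
}

sel_parse_and <- function(env, structure) {
  m <- sel_parse_unary(env, structure)
  while (!is.na(sel_peek(env)) && tolower(sel_peek(env)) == "and") {
    sel_next(env)
    m <- m & sel_parse_unary(env, structure)
  }
  m
}

sel_parse_unary <- function(env, structure) {
  v <- sel_peek(env)
  if (is.na(v)) sel_err(env, "expected a term")
  if (tolower(v) == "not") {
    sel_next(env)
    return(!sel_parse_unary(env, structure))
  }
  sel_parse_primary(env, structure)
}

sel_parse_primary <- function(env, structure) {
  v <- sel_peek(env)
  if (is.na(v)) sel_err(env, "expected a term")
  if (v == "(") {
    sel_next(env)
    m <- sel_parse_or(env, structure)
    if (is.na(sel_peek(env)) || sel_peek(env) != ")")
      sel_err(env, "expected ')'")
    sel_next(env)
    return(m)
  }
  sel_parse_term(env, structure)
}

sel_parse_term <- function(env, structure) {
  at <- structure$atoms
  res <- structure$residues
  ch <- structure$chains
  kw <- tolower(sel_next(env))
  switch(kw,
    chain = {
      id <- sel_next(env)
      m <- at$auth_asym_id == id
      if (!any(m)) m <- at$asym_id == id
      m
    },
    resi = {
      rng <- sel_next(env)
      if (!grepl("^-?[0-9]+(--?[0-9]+)?$", rng))
        sel_err(env, sprintf("bad residue range '%s'", rng))
      parts <- regmatches(rng, regexec("^(-?[0-9]+)(?:-(-?[0-9]+))?$", rng))[[1L]]
      lo <- as.integer(parts[[2L]])
      hi <- if (nzchar(parts[[3L]])) as.integer(parts[[3L]]) else lo
      at$seq_id >= lo & at$seq_id <= hi
    },
    resn = {
      nm <- toupper(sel_next(env))
      toupper(at$comp_id) == nm
    },
    name = {
      nm <- toupper(sel_next(env))
      toupper(at$name) == nm
    },
    hetero = at$is_hetero,
    polymer = {
      mt <- ch$moltype[res$chain_index[at$residue_index]]
      mt %in% c("polypeptide", "nucleic") & !at$is_hetero
    },
    {
      env$st$pos <- env$st$pos - 1L
      sel_err(env, sprintf(
        "unknown term '%s' (expected chain/resi/resn/name/hetero/polymer)", kw))
    })
}
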