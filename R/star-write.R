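#' Write blocks as an mmCIF document
#'
#' The output re-parses to value-identical blocks: nulls are written as `?`,
#' text needing protection is quoted (or emitted as a semicolon text field
#' when it contains a newline or both quote characters), and categories with
#' more than one row are written as `loop_` tables.
#'
#' @param blocks a [cif_block()] or list of them.
#' @param path optional output file; `.gz` suffix triggers gzip compression.
#' @return the document as a single string (invisibly when `path` is given).
#' @export
write_mmcif <- function(blocks, path = NULL) {
  if (inherits(blocks, "cif_block")) blocks <- list(blocks)
  out <- character(0)
  for (b in blocks) {
    out <- c(out, paste0("data_", b$name), "#")
    for (cc in b$categories) {
      nr <- cif_nrows(cc)
      tags <- paste0("_", cc$name, ".", names(cc$columns))
      if (nr == 1L && length(cc$columns)) {
        w <- max(nchar(tags)) + 3L
        for (j in seq_along(cc$columns)) {
          val <- mmcif_format_value(cc$columns[[j]][[1L]])
          if (startsWith(val, ";")) {
            out <- c(out, tags[j], val)
          } else {
            out <- c(out, sprintf("%-*s%s", w, tags[j], val))
          }
        }
      } else {
        out <- c(out, "loop_", tags)
        for (r in seq_len(nr)) {
          row <- vapply(cc$columns, function(col)
            mmcif_format_value(col[[r]]), "")
          if (any(startsWith(row, ";"))) {
            # any semicolon field forces one value per line for this row
            for (v in row) out <- c(out, v)
          } else {
            out <- c(out, paste(row, collapse = " "))
          }
        }
      }
      out <- c(out, "#")
    }
  }
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
    writeBin(charToRaw(txt), con)
    close(con)
    return(invisible(txt))
  }
  txt
}

# Format one cell as an mmCIF token (possibly a multi-line ";" field).
mmcif_format_value <- function(x) {
  if (is.null(x)) return("?")
  if (is.numeric(x)) {
    if (is.integer(x) || (is.finite(x) && x == floor(x) && abs(x) < 1e15))
      return(sprintf("%.0f", as.numeric(x)))
    return(sprintf("%.15g", x))
  }
  s <- as.character(x)
  has_nl <- grepl("\n", s, fixed = TRUE)
  has_sq <- grepl("'", s, fixed = TRUE)
  has_dq <- grepl('"', s, fixed = TRUE)
  if (has_nl || (has_sq && has_dq))
    return(paste0(";", s, "\n;"))
  needs_quote <- !nzchar(s) ||
    grepl("[ \t]", s) ||
    has_sq || has_dq ||
    startsWith(s, "_") || startsWith(s, "#") || startsWith(s, "$") ||
    startsWith(s, "[") || startsWith(s, "]") || startsWith(s, ";") ||
    grepl("^(data_|loop_$|save_|global_|stop_$)", s, ignore.case = TRUE) ||
    # would re-parse as null or number: protect text-ness
    !identical(star_typed_value(s), s)
  if (!needs_quote) return(s)
  if (!has_sq) return(paste0("'", s, "'"))
  paste0('"', s, '"')
}
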