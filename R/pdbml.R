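#' Parse a PDBML (PDBx XML) document
#'
#' PDBML serializes each mmCIF category as a `<X:nameCategory>` element
#' wrapping one row element per table row; key items appear as row
#' attributes, remaining items as child elements. This reader maps that tree
#' back onto the STAR model: attributes and child-element texts become cells
#' (typed exactly as mmCIF tokens are), a child missing from one row but
#' present in another becomes a null cell, and `xsi:nil` children are null.
#'
#' @param text XML document string.
#' @param path alternatively a file path (gzip detected by magic bytes).
#' @return list with one [cif_block()] (PDBML files hold a single datablock).
#' @export
parse_pdbml <- function(text = NULL, path = NULL) {
  if (is.null(text)) text <- read_text_auto(path)
  doc <- xml2::read_xml(text)
  root <- xml2::xml_ns_strip(doc)
  name <- xml2::xml_attr(root, "datablockName")
  if (is.na(name) || !nzchar(name))
    name <- xml2::xml_attr(root, "name")
  if (is.na(name) || !nzchar(name)) name <- "unnamed"
  cat_nodes <- xml2::xml_find_all(root, "./*")
  categories <- list()
  for (cn in cat_nodes) {
    tag <- xml2::xml_name(cn)
    if (!grepl("Category$", tag)) next
    catname <- sub("Category$", "", tag)
    rows <- xml2::xml_find_all(cn, "./*")
    rows <- rows[xml2::xml_name(rows) == catname]
    keys <- character(0)
    cells <- list()  # key -> list of cells per row index
    nr <- length(rows)
    for (r in seq_len(nr)) {
      row <- rows[[r]]
      at <- xml2::xml_attrs(row)
      at <- at[!grepl("^(xmlns|xsi)", names(at))]
      for (k in names(at)) {
        if (!k %in% keys) { keys <- c(keys, k); cells[[k]] <- vector("list", nr) }
        cells[[k]][r] <- list(star_typed_value(at[[k]]))
      }
      for (ch in xml2::xml_find_all(row, "./*")) {
        k <- xml2::xml_name(ch)
        if (!k %in% keys) { keys <- c(keys, k); cells[[k]] <- vector("list", nr) }
        nil <- xml2::xml_attr(ch, "nil")
        val <- if (!is.na(nil) && nil %in% c("true", "1")) NULL
               else star_typed_value(xml2::xml_text(ch))
        cells[[k]][r] <- list(val)
      }
    }
    categories[[length(categories) + 1L]] <-
      cif_category(catname, cells[keys])
  }
  list(cif_block(name, categories))
}
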