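#' Convert blocks to PDBx/mmJSON
#'
#' mmJSON is a direct JSON rendering of the STAR data model: the top-level
#' object maps `data_<blockname>` to an object of categories; each category
#' maps item keywords to column arrays. Numeric tokens become JSON numbers
#' (integers stay integral); both `?` and `.` become JSON `null`. All
#' categories are column-major, including single-row ones.
#'
#' @param blocks a [cif_block()] or list of them.
#' @param path optional output file; `.gz` suffix triggers gzip compression.
#' @param pretty pretty-print the JSON.
#' @return JSON document as a single string.
#' @examples
#' b <- parse_mmcif("data_TOY\n_cell.length_a 10.5\n")
#' to_mmjson(b)
#' @export
to_mmjson <- function(blocks, path = NULL, pretty = FALSE) {
  if (inherits(blocks, "cif_block")) blocks <- list(blocks)
  top <- list()
  for (b in blocks) {
    cats <- structure(list(), names = character(0))
    for (cc in b$categories) {
      cols <- structure(list(), names = character(0))
      for (kn in names(cc$columns)) {
        col <- cc$columns[[kn]]
        # each cell is a length-1 atomic (unboxed) or NULL (-> null)
        cols[[kn]] <- lapply(col, function(x) {
          if (is.null(x)) NULL
          else if (is.numeric(x) && !is.integer(x) &&
                   is.finite(x) && x == floor(x) &&
                   abs(x) <= .Machine$integer.max) as.integer(x)
          else x
        })
      }
      cats[[cc$name]] <- cols
    }
    top[[paste0("data_", b$name)]] <- cats
  }
  txt <- as.character(jsonlite::toJSON(top, auto_unbox = TRUE, null = "null",
                                       na = "null", digits = NA,
                                       pretty = pretty))
  if (!is.null(path)) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
    writeBin(charToRaw(txt), con)
    close(con)
    return(invisible(txt))
  }
  txt
}

#' Parse a PDBx/mmJSON document
#'
#' Inverse of [to_mmjson()] up to the `?` / `.` distinction, which mmJSON
#' collapses into `null` (re-serialized as `?`).
#'
#' @param text JSON document string.
#' @param path alternatively a file path (gzip detected by magic bytes).
#' @return list of [cif_block()] objects.
#' @export
from_mmjson <- function(text = NULL, path = NULL) {
  if (is.null(text)) text <- read_text_auto(path)
  top <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  if (!length(top)) stop("mmJSON document has no data blocks")
  if (is.null(names(top)) || !all(startsWith(names(top), "data_")))
    stop("mmJSON top-level keys must all start with 'data_'")
  lapply(names(top), function(bk) {
    cats <- top[[bk]]
    categories <- lapply(names2(cats), function(cn) {
      cols <- cats[[cn]]
      lens <- lengths(cols)
      if (length(unique(lens)) > 1L)
        stop(sprintf("ragged category '%s' in mmJSON: column lengths %s",
                     cn, paste(lens, collapse = ", ")))
      cif_category(cn, lapply(cols, function(col) {
        lapply(col, function(x) {
          if (is.null(x)) NULL
          else if (is.numeric(x)) x       # jsonlite: 3 -> integer, 3.5 -> double
          else as.character(x)
        })
      }))
    })
    cif_block(substring(bk, 6L), categories)
  })
}

names2 <- function(x) if (is.null(names(x))) character(0) else names(x)

# amino-acid trace atom is CA, nucleotide trace atom is P
LITE_ITEMS <- c("group_PDB", "label_atom_id", "label_comp_id", "label_asym_id",
                "auth_asym_id", "label_seq_id", "auth_seq_id",
                "Cartn_x", "Cartn_y", "Cartn_z", "pdbx_PDB_model_num")

#' Write backbone-only "lite" mmJSON
#'
#' Produces a valid mmJSON document restricted to the minimum needed to draw
#' a backbone trace: `atom_site` rows are filtered to trace atoms (CA for
#' amino acids, P for nucleotides), items are restricted to a minimal
#' whitelist, and only the secondary-structure categories `struct_conf` and
#' `struct_sheet_range` are carried along; everything else is dropped.
#'
#' @param blocks a [cif_block()] or list of them; must contain `atom_site`.
#' @param path optional output file.
#' @return JSON document string.
#' @export
write_mmjson_lite <- function(blocks, path = NULL) {
  if (inherits(blocks, "cif_block")) blocks <- list(blocks)
  lite <- lapply(blocks, function(b) {
    as <- b$categories[["atom_site"]]
    if (is.null(as)) stop(sprintf("block '%s' has no atom_site category", b$name))
    nr <- cif_nrows(as)
    atom_id <- column_chr(as, "label_atom_id", nr)
    group <- column_chr(as, "group_PDB", nr)
    keep <- atom_id %in% c("CA", "P")
    if (!all(is.na(group))) keep <- keep & (group == "ATOM" | is.na(group))
    cols <- as$columns[intersect(LITE_ITEMS, names(as$columns))]
    cols <- lapply(cols, function(col) col[keep])
    cats <- list(cif_category("atom_site", cols))
    for (extra in c("struct_conf", "struct_sheet_range"))
      if (!is.null(b$categories[[extra]]))
        cats[[length(cats) + 1L]] <- b$categories[[extra]]
    cif_block(b$name, cats)
  })
  to_mmjson(lite, path = path)
}

# Extract a category column as character with NA for nulls/missing column.
column_chr <- function(cat, key, nr = cif_nrows(cat)) {
  col <- cat$columns[[key]]
  if (is.null(col)) return(rep(NA_character_, nr))
  vapply(col, function(x) if (is.null(x)) NA_character_ else as.character(x), "")
}

# Numeric version of column_chr.
column_num <- function(cat, key, nr = cif_nrows(cat)) {
  col <- cat$columns[[key]]
  if (is.null(col)) return(rep(NA_real_, nr))
  vapply(col, function(x) {
    if (is.null(x)) return(NA_real_)
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) NA_real_ else v
  }, 0.0)
}

#' Compare compressed sizes of mmCIF, PDBML and mmJSON per entry
#'
#' For every entry in a corpus directory that has both an mmCIF (`.cif`) and
#' a PDBML (`.xml`) file, computes the gzip-compressed byte sizes of the two
#' source files and of the mmJSON produced from the mmCIF, and the relative
#' size reduction `100 * (1 - size_mmjson / size_other)` of mmJSON against
#' each.
#'
#' @param dir corpus directory containing `<entry>.cif` and `<entry>.xml`
#'   pairs (optionally gzipped).
#' @param level gzip compression level (1-9).
#' @return a data.frame with one row per entry (columns `entry`,
#'   `gz_mmcif`, `gz_pdbml`, `gz_mmjson`, `red_vs_mmcif`, `red_vs_pdbml`)
#'   carrying the mean reductions as attributes `mean_vs_mmcif` and
#'   `mean_vs_pdbml` (`NA` for an empty corpus).
#' @export
compare_compressed_sizes <- function(dir, level = 6L) {
  files <- list.files(dir, full.names = TRUE)
  stem <- sub("\\.gz$", "", basename(files))
  entries <- sort(unique(tools::file_path_sans_ext(stem)))
  rows <- list()
  skipped <- character(0)
  for (e in entries) {
    cif <- files[stem == paste0(e, ".cif")]
    xml <- files[stem == paste0(e, ".xml")]
    if (!length(cif) || !length(xml)) next
    rec <- tryCatch({
      cif_txt <- read_text_auto(cif[[1L]])
      xml_txt <- read_text_auto(xml[[1L]])
      json_txt <- to_mmjson(parse_mmcif(cif_txt))
      gz <- function(txt) length(memCompress(charToRaw(txt), "gzip"))
      c(gz(cif_txt), gz(xml_txt), gz(json_txt))
    }, error = function(err) {
      warning(sprintf("entry '%s' skipped: %s", e, conditionMessage(err)))
      NULL
    })
    if (is.null(rec)) skipped <- c(skipped, e) else rows[[e]] <- rec
  }
  if (!length(rows)) {
    tab <- data.frame(entry = character(0), gz_mmcif = numeric(0),
                      gz_pdbml = numeric(0), gz_mmjson = numeric(0),
                      red_vs_mmcif = numeric(0), red_vs_pdbml = numeric(0))
    attr(tab, "mean_vs_mmcif") <- NA_real_
    attr(tab, "mean_vs_pdbml") <- NA_real_
    attr(tab, "skipped") <- skipped
    return(tab)
  }
  m <- do.call(rbind, rows)
  tab <- data.frame(entry = names(rows),
                    gz_mmcif = m[, 1L], gz_pdbml = m[, 2L], gz_mmjson = m[, 3L],
                    red_vs_mmcif = 100 * (1 - m[, 3L] / m[, 1L]),
                    red_vs_pdbml = 100 * (1 - m[, 3L] / m[, 2L]),
                    row.names = NULL)
  attr(tab, "mean_vs_mmcif") <- mean(tab$red_vs_mmcif)
  attr(tab, "mean_vs_pdbml") <- mean(tab$red_vs_pdbml)
  attr(tab, "skipped") <- skipped
  tab
}
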