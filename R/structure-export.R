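#' Convert a structure back to PDBx blocks
#'
#' Builds an `atom_site` category (plus `struct_conf` / `struct_sheet_range`
#' for annotated runs) from a `molstruct`, so any reader's output can be
#' re-serialized as mmCIF or mmJSON.
#'
#' @param structure a `molstruct`.
#' @return list with one [cif_block()].
#' @export
structure_to_blocks <- function(structure) {
  at <- structure$atoms
  res <- structure$residues
  n <- nrow(at)
  nm <- length(structure$coords)
  cols <- list(
    group_PDB = as.list(ifelse(at$is_hetero, "HETATM", "ATOM")),
    id = as.list(rep(seq_len(n), nm) |> as.integer()),
    type_symbol = as.list(at$element),
    label_atom_id = as.list(at$name),
    label_comp_id = as.list(at$comp_id),
    label_asym_id = as.list(at$asym_id),
    auth_asym_id = as.list(at$auth_asym_id),
    label_seq_id = as.list(as.integer(at$seq_id)),
    auth_seq_id = as.list(as.integer(at$seq_id)),
    Cartn_x = list(), Cartn_y = list(), Cartn_z = list(),
    occupancy = as.list(at$occupancy),
    B_iso_or_equiv = as.list(at$b_factor),
    pdbx_PDB_model_num = as.list(rep(1L, n)))
  # replicate topology columns across models, vary coords and model number
  rep_col <- function(col) rep(col, nm)
  if (nm > 1L) {
    for (k in setdiff(names(cols), c("Cartn_x", "Cartn_y", "Cartn_z",
                                     "pdbx_PDB_model_num", "id")))
      cols[[k]] <- rep_col(cols[[k]])
    cols$pdbx_PDB_model_num <- as.list(rep(seq_len(nm), each = n))
    cols$id <- as.list(seq_len(n * nm))
  } else {
    cols$id <- as.list(seq_len(n))
  }
  xyz <- do.call(rbind, structure$coords)
  cols$Cartn_x <- as.list(round(xyz[, 1L], 4))
  cols$Cartn_y <- as.list(round(xyz[, 2L], 4))
  cols$Cartn_z <- as.list(round(xyz[, 3L], 4))
  cats <- list(cif_category("atom_site", cols))
  # secondary-structure ranges
  runs <- list()
  for (ci in seq_len(nrow(structure$chains))) {
    rix <- which(res$chain_index == ci)
    r <- rle(res$ss[rix])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (g in seq_along(r$values)) {
      if (r$values[[g]] == "coil") next
      runs[[length(runs) + 1L]] <- list(
        kind = r$values[[g]], asym = structure$chains$asym_id[ci],
        beg = res$seq_id[rix[starts[g]]], end = res$seq_id[rix[ends[g]]])
    }
  }
  helices <- Filter(function(x) x$kind == "helix", runs)
  sheets <- Filter(function(x) x$kind == "sheet", runs)
  if (length(helices)) {
    cats[[length(cats) + 1L]] <- cif_category("struct_conf", list(
      conf_type_id = as.list(rep("HELX_P", length(helices))),
      id = as.list(seq_along(helices)),
      beg_label_asym_id = lapply(helices, `[[`, "asym"),
      beg_auth_seq_id = lapply(helices, `[[`, "beg"),
      end_label_asym_id = lapply(helices, `[[`, "asym"),
      end_auth_seq_id = lapply(helices, `[[`, "end")))
  }
  if (length(sheets)) {
    cats[[length(cats) + 1L]] <- cif_category("struct_sheet_range", list(
      sheet_id = as.list(rep("A", length(sheets))),
      id = as.list(seq_along(sheets)),
      beg_label_asym_id = lapply(sheets, `[[`, "asym"),
      beg_auth_seq_id = lapply(sheets, `[[`, "beg"),
      end_label_asym_id = lapply(sheets, `[[`, "asym"),
      end_auth_seq_id = lapply(sheets, `[[`, "end")))
  }
  list(cif_block(if (nzchar(structure$entry_id)) structure$entry_id else "XXXX",
                 cats))
}
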