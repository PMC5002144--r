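#' Parse an mmCIF / STAR document
#'
#' Parses one or more `data_` blocks into the in-memory STAR model. Tag/value
#' pairs and `loop_` tables both become categories with column-major columns;
#' a non-loop item yields a one-row category. Single- and double-quoted
#' strings and semicolon text fields are resolved; `#` comments are stripped.
#' `save_` frames, dictionaries and `global_` blocks are rejected: this is a
#' coordinate-file codec, not a dictionary tool.
#'
#' @param text mmCIF document as a single string (or character vector of
#'   lines).
#' @param path alternatively, a file path; gzip input is detected by its
#'   magic bytes and decompressed transparently.
#' @return list of [cif_block()] objects.
#' @examples
#' b <- parse_mmcif("data_TOY\n_cell.length_a 10.5\n")[[1]]
#' b$categories$cell$columns$length_a[[1]]  # 10.5
#' @export
parse_mmcif <- function(text = NULL, path = NULL) {
  if (is.null(text)) {
    stopifnot(!is.null(path))
    text <- read_text_auto(path)
  }
  if (length(text) > 1L) text <- paste(text, collapse = "\n")
  toks <- star_tokenize(text)
  star_parse_tokens(toks)
}

# --- tokenizer -------------------------------------------------------------
# Returns a data.frame: value, quoted (logical), line (integer).
star_tokenize <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  vals <- character(0); quoted <- logical(0); lineno <- integer(0)
  n <- length(lines)
  i <- 1L
  push <- function(v, q, l) {
    vals[[length(vals) + 1L]] <<- v
    quoted[[length(quoted) + 1L]] <<- q
    lineno[[length(lineno) + 1L]] <<- l
  }
  while (i <= n) {
    line <- lines[[i]]
    if (startsWith(line, ";")) {
      # semicolon text field: body runs until a line starting with ";"
      start <- i
      body <- substring(line, 2L)
      i <- i + 1L
      found <- FALSE
      acc <- character(0)
      while (i <= n) {
        if (startsWith(lines[[i]], ";")) { found <- TRUE; break }
        acc[[length(acc) + 1L]] <- lines[[i]]
        i <- i + 1L
      }
      if (!found) stop(sprintf("line %d: unterminated text field", start))
      push(paste(c(body, acc), collapse = "\n"), TRUE, start)
      rest <- substring(lines[[i]], 2L)
      i <- i + 1L
      if (nzchar(trimws(rest))) {
        for (tk in star_tokenize_line(rest, i - 1L)) push(tk$v, tk$q, i - 1L)
      }
      next
    }
    for (tk in star_tokenize_line(line, i)) push(tk$v, tk$q, i)
    i <- i + 1L
  }
  data.frame(value = vals, quoted = quoted, line = lineno,
             stringsAsFactors = FALSE)
}

# Tokenize a single physical line (no semicolon fields here).
star_tokenize_line <- function(line, lineno) {
  out <- list()
  chars <- strsplit(line, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  j <- 1L
  while (j <= n) {
    c0 <- chars[[j]]
    if (c0 == " " || c0 == "\t" || c0 == "\r") { j <- j + 1L; next }
    if (c0 == "#") break  # comment to end of line
    if (c0 == "'" || c0 == '"') {
      q <- c0
      k <- j + 1L
      val <- character(0)
      repeat {
        if (k > n) stop(sprintf("line %d: unterminated quoted string", lineno))
        if (chars[[k]] == q &&
            (k == n || chars[[k + 1L]] %in% c(" ", "\t", "\r"))) break
        val[[length(val) + 1L]] <- chars[[k]]
        k <- k + 1L
      }
      out[[length(out) + 1L]] <- list(v = paste(val, collapse = ""), q = TRUE)
      j <- k + 1L
      next
    }
    k <- j
    while (k <= n && !(chars[[k]] %in% c(" ", "\t", "\r"))) k <- k + 1L
    out[[length(out) + 1L]] <-
      list(v = paste(chars[j:(k - 1L)], collapse = ""), q = FALSE)
    j <- k
  }
  out
}

is_tag <- function(tok) !tok$quoted & startsWith(tok$value, "_")

# --- grammar ---------------------------------------------------------------
star_parse_tokens <- function(toks) {
  n <- nrow(toks)
  if (n == 0L) stop("empty document: no data_ block found")
  blocks <- list()
  i <- 1L
  # skip anything before the first data_ (should be nothing but comments)
  first <- toks$value[i]
  if (toks$quoted[i] || !grepl("^data_", first, ignore.case = TRUE))
    stop(sprintf("line %d: expected data_ block, got '%s'",
                 toks$line[i], first))
  while (i <= n) {
    v <- toks$value[i]; q <- toks$quoted[i]
    if (!q && grepl("^global_$", v, ignore.case = TRUE))
      stop(sprintf("line %d: global_ blocks are not supported", toks$line[i]))
    if (!q && grepl("^save_", v, ignore.case = TRUE))
      stop(sprintf("line %d: save_ frames are not supported", toks$line[i]))
    if (!q && grepl("^data_", v, ignore.case = TRUE)) {
      name <- substring(v, 6L)
      if (!nzchar(name))
        stop(sprintf("line %d: empty data_ block name", toks$line[i]))
      res <- star_parse_block(toks, i + 1L, name)
      blocks[[length(blocks) + 1L]] <- res$block
      i <- res$next_i
    } else {
      stop(sprintf("line %d: unexpected token '%s' outside a block",
                   toks$line[i], v))
    }
  }
  blocks
}

star_split_tag <- function(tag, line) {
  body <- substring(tag, 2L)
  dot <- regexpr(".", body, fixed = TRUE)
  if (dot < 1L)
    stop(sprintf("line %d: item '%s' has no category.keyword form", line, tag))
  list(cat = substring(body, 1L, dot - 1L),
       key = substring(body, dot + 1L))
}

star_parse_block <- function(toks, i, name) {
  n <- nrow(toks)
  cats <- list()        # name -> named list of columns (lists of cells)
  cat_order <- character(0)
  add_cell <- function(catname, key, cell) {
    if (is.null(cats[[catname]])) {
      cats[[catname]] <<- list()
      cat_order[[length(cat_order) + 1L]] <<- catname
    }
    col <- cats[[catname]][[key]]
    if (is.null(col)) col <- list()
    col[length(col) + 1L] <- list(cell)   # list() wrapper so NULL cells append
    cats[[catname]][[key]] <<- col
  }
  value_of <- function(k) {
    if (toks$quoted[k]) toks$value[k] else star_typed_value(toks$value[k])
  }
  is_reserved <- function(k) {
    !toks$quoted[k] &&
      grepl("^(data_|loop_$|save_|global_|stop_$)", toks$value[k],
            ignore.case = TRUE)
  }
  while (i <= n) {
    v <- toks$value[i]; q <- toks$quoted[i]
    if (!q && grepl("^data_", v, ignore.case = TRUE)) break
    if (!q && grepl("^(save_|global_)", v, ignore.case = TRUE))
      stop(sprintf("line %d: %s not supported", toks$line[i],
                   sub("_.*", "_ frames/blocks", v)))
    if (!q && grepl("^loop_$", v, ignore.case = TRUE)) {
      loop_line <- toks$line[i]
      i <- i + 1L
      tags <- list()
      while (i <= n && !toks$quoted[i] && startsWith(toks$value[i], "_")) {
        tags[[length(tags) + 1L]] <- star_split_tag(toks$value[i], toks$line[i])
        i <- i + 1L
      }
      if (!length(tags))
        stop(sprintf("line %d: loop_ without item tags", loop_line))
      catname <- tags[[1L]]$cat
      if (!all(vapply(tags, function(t) t$cat, "") == catname))
        stop(sprintf("line %d: loop_ mixes categories", loop_line))
      nvals <- 0L
      start_val <- i
      while (i <= n && !is_tag(toks[i, ]) && !is_reserved(i)) {
        nvals <- nvals + 1L
        i <- i + 1L
      }
      ncol <- length(tags)
      if (nvals %% ncol != 0L)
        stop(sprintf(
          "line %d: malformed loop_ for category '%s': %d values not a multiple of %d columns",
          if (i <= n) toks$line[i - 1L] else toks$line[n], catname, nvals, ncol))
      if (nvals > 0L) {
        ks <- start_val:(start_val + nvals - 1L)
        for (r in seq_len(nvals %/% ncol)) {
          for (cix in seq_len(ncol)) {
            k <- ks[(r - 1L) * ncol + cix]
            add_cell(catname, tags[[cix]]$key, value_of(k))
          }
        }
      } else {
        if (is.null(cats[[catname]])) {
          cats[[catname]] <- list()
          cat_order[[length(cat_order) + 1L]] <- catname
        }
        for (t in tags)
          if (is.null(cats[[catname]][[t$key]]))
            cats[[catname]][[t$key]] <- list()  # 0-row column
      }
      next
    }
    if (!q && startsWith(v, "_")) {
      tg <- star_split_tag(v, toks$line[i])
      if (i + 1L > n || is_tag(toks[i + 1L, ]) || is_reserved(i + 1L))
        stop(sprintf("line %d: item %s has no value", toks$line[i], v))
      add_cell(tg$cat, tg$key, value_of(i + 1L))
      i <- i + 2L
      next
    }
    stop(sprintf("line %d: unexpected value token '%s'", toks$line[i], v))
  }
  categories <- lapply(cat_order, function(cn) {
    cols <- cats[[cn]]
    lens <- lengths(cols)
    if (length(unique(lens)) > 1L)
      stop(sprintf("category '%s': inconsistent row counts (%s)", cn,
                   paste(lens, collapse = ", ")))
    cif_category(cn, cols)
  })
  list(block = cif_block(name, categories), next_i = i)
}
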