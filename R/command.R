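#' @title Command language
#' @description
#' A small, closed command language over the toolkit: loading and fetching
#' structures, showing/hiding representations, colouring, snapshots and
#' movie frames, plus URL-fragment command extraction for shareable links.
#' Unlike a host-language command line, the verb set is closed, so scripts
#' are safe to execute and fully testable. PyMOL-style argument order is
#' accepted for `show` / `hide` / `color` / `select`.
#' @name command-shell
NULL

COMMAND_VERBS <- c("load", "fetch", "show", "hide", "color", "select",
                   "snapshot", "movie", "set")

#' Parse one command line
#'
#' Grammar: `<verb> <args...> [, key=value | , <selection>]`. The
#' function-call forms `molmil.loadPDB('id')` and `molmil.loadPDBlite('id')`
#' are accepted and map to `fetch` (the lite variant sets `lite = TRUE`).
#' A bare post-comma argument is the selection (PyMOL argument order).
#'
#' @param text a single command line.
#' @return an object of class `molcmd`: list with `verb`, `args`
#'   (character vector) and `options` (named list).
#' @export
parse_command <- function(text) {
  s <- trimws(text)
  if (!nzchar(s)) stop("empty command")
  m <- regmatches(s, regexec("^molmil\\.([A-Za-z_]+)\\((.*)\\)$", s))[[1L]]
  if (length(m)) {
    fn <- m[[2L]]; arg <- trimws(m[[3L]])
    arg <- gsub("^['\"‘“]|['\"’”]$", "", arg)
    if (fn == "loadPDB") return(new_command("fetch", arg))
    if (fn == "loadPDBlite")
      return(new_command("fetch", arg, list(lite = TRUE)))
    if (fn == "loadFile") return(new_command("load", arg))
    stop(sprintf("unknown function command 'molmil.%s'", fn))
  }
  parts <- split_top_commas(s)
  head <- cmd_tokens(parts[[1L]])
  if (!length(head)) stop("empty command")
  verb <- tolower(head[[1L]])
  if (!verb %in% COMMAND_VERBS)
    stop(sprintf("unknown verb '%s' (valid: %s)", verb,
                 paste(COMMAND_VERBS, collapse = ", ")))
  args <- if (length(head) > 1L) head[-1L] else character(0)
  options <- list()
  for (p in parts[-1L]) {
    p <- trimws(p)
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq > 0L) {
      key <- trimws(substr(p, 1L, eq - 1L))
      val <- trimws(substr(p, eq + 1L, nchar(p)))
      val <- strip_quotes(val)
      options[[key]] <- utils::type.convert(val, as.is = TRUE)
    } else {
      options[["selection"]] <- p
    }
  }
  new_command(verb, args, options)
}

new_command <- function(verb, args = character(0), options = list()) {
  structure(list(verb = verb, args = as.character(args), options = options),
            class = "molcmd")
}

#' @export
print.molcmd <- function(x, ...) {
  cat(sprintf("<molcmd> %s\n", format_command(x)))
  invisible(x)
}

#' Format a command back to its line form
#'
#' Inverse of [parse_command()] on the command model:
#' `parse_command(format_command(cmd))` equals `cmd`.
#'
#' @param cmd a `molcmd`.
#' @return single command line string.
#' @export
format_command <- function(cmd) {
  quote_arg <- function(a) {
    if (grepl("[ ,]", a) || !nzchar(a)) paste0("'", a, "'") else a
  }
  out <- paste(c(cmd$verb, vapply(cmd$args, quote_arg, "")), collapse = " ")
  for (key in names(cmd$options)) {
    v <- cmd$options[[key]]
    part <- if (key == "selection") paste(v)
            else paste0(key, "=", if (is.character(v) && grepl("[ ,]", v))
                                    paste0("'", v, "'") else paste(v))
    out <- paste0(out, ", ", part)
  }
  out
}

# split on commas that are not inside quotes
split_top_commas <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  parts <- character(0); buf <- character(0); q <- ""
  for (ch in chars) {
    if (nzchar(q)) {
      if (ch == q) q <- ""
      buf <- c(buf, ch)
    } else if (ch == "'" || ch == '"') {
      q <- ch; buf <- c(buf, ch)
    } else if (ch == ",") {
      parts <- c(parts, paste(buf, collapse = "")); buf <- character(0)
    } else buf <- c(buf, ch)
  }
  if (nzchar(q)) stop(sprintf("malformed quoting in command at position %d",
                              nchar(s)))
  c(parts, paste(buf, collapse = ""))
}

# whitespace tokenizer with quote support; reports error position
cmd_tokens <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  out <- character(0); i <- 1L; n <- length(chars)
  while (i <= n) {
    if (chars[[i]] %in% c(" ", "\t")) { i <- i + 1L; next }
    if (chars[[i]] %in% c("'", '"')) {
      q <- chars[[i]]; j <- i + 1L
      while (j <= n && chars[[j]] != q) j <- j + 1L
      if (j > n) stop(sprintf("unterminated quote at position %d", i))
      out <- c(out, paste(chars[seq(i + 1L, length.out = j - i - 1L)],
                          collapse = ""))
      i <- j + 1L
    } else {
      j <- i
      while (j <= n && !(chars[[j]] %in% c(" ", "\t"))) j <- j + 1L
      out <- c(out, paste(chars[i:(j - 1L)], collapse = ""))
      i <- j
    }
  }
  out
}

strip_quotes <- function(s) gsub("^['\"]|['\"]$", "", s)

#' Extract commands from a URL fragment
#'
#' The fragment after `#` is split on `;`, percent-decoded, and each piece
#' parsed with [parse_command()]. No fragment (or an empty one) gives an
#' empty list.
#'
#' @param url a URL.
#' @return list of `molcmd` objects.
#' @export
parse_url_fragment <- function(url) {
  hash <- regexpr("#", url, fixed = TRUE)
  if (hash < 0L) return(list())
  frag <- substring(url, hash + 1L)
  if (!nzchar(frag)) return(list())
  pieces <- trimws(strsplit(frag, ";", fixed = TRUE)[[1L]])
  lapply(unname(pieces[nzchar(pieces)]), function(p) {
    # decode per argument so encoded spaces stay inside one token
    cmd <- parse_command(p)
    cmd$args <- vapply(cmd$args, utils::URLdecode, "", USE.NAMES = FALSE)
    cmd$options <- lapply(cmd$options, function(v)
      if (is.character(v)) utils::URLdecode(v) else v)
    cmd
  })
}

#' Create a fresh session
#'
#' @param fetch_dir directory used by `fetch` to resolve entry ids to local
#'   files (`<id>.cif` / `.json` / `.pdb`, optionally gzipped); defaults to
#'   the packaged fixture mirror.
#' @return an object of class `molsession`.
#' @export
new_session <- function(fetch_dir = NULL) {
  if (is.null(fetch_dir))
    fetch_dir <- system.file("extdata", "mirror", package = "molviewr")
  structure(list(
    structures = list(), selections = list(), trajectory = NULL,
    shown = list(), colors = list(),
    material = new_material(), detail = NULL,
    width = 320L, height = 240L,
    fetch_dir = fetch_dir, log = character(0)), class = "molsession")
}

#' @export
print.molsession <- function(x, ...) {
  cat(sprintf("<molsession> %d structure(s), %d shown, %d log entries\n",
              length(x$structures), length(x$shown), length(x$log)))
  invisible(x)
}

session_log <- function(session, fmt, ...) {
  session$log <- c(session$log, sprintf(fmt, ...))
  session
}

last_structure_name <- function(session) {
  if (!length(session$structures)) stop("no structure loaded")
  names(session$structures)[[length(session$structures)]]
}

#' Execute a command against a session
#'
#' `load` reads a local file through the codec chosen by extension; `fetch`
#' resolves an entry id in the session's mirror directory; `show` / `hide`
#' toggle representation assignments; `color` applies a scheme or literal
#' colour; `select` stores a named selection; `set` updates
#' material/render settings; `snapshot` renders the current state to a PNG;
#' `movie` renders trajectory frames. All effects are logged.
#'
#' @param command a `molcmd` (or command line string).
#' @param session a `molsession`.
#' @return the updated session.
#' @export
execute <- function(command, session = new_session()) {
  if (is.character(command)) command <- parse_command(command)
  verb <- command$verb
  args <- command$args
  opt <- command$options
  sel_of <- function() if (is.null(opt$selection)) NULL else opt$selection
  switch(verb,
    load = {
      path <- args[[1L]]
      if (!file.exists(path)) stop(sprintf("no such file: %s", path))
      st <- read_structure_any(path)
      nm <- opt$name %||% tools::file_path_sans_ext(basename(path))
      if (inherits(st, "moltraj")) {
        session$trajectory <- st
        session <- session_log(session, "load trajectory %s (%d frames)",
                               path, length(st$frames))
      } else {
        session$structures[[nm]] <- st
        session <- session_log(session, "load %s as %s (%d atoms)", path, nm,
                               n_atoms(st))
      }
      session
    },
    fetch = {
      id <- args[[1L]]
      dir <- session$fetch_dir
      if (is.null(dir) || !nzchar(dir) || !dir.exists(dir))
        stop(paste0("fetch source not configured: create a session with ",
                    "new_session(fetch_dir = <local mirror directory>)"))
      cand <- c(paste0(id, c(".cif", ".json", ".xml", ".pdb")),
                paste0(id, c(".cif.gz", ".json.gz", ".xml.gz", ".pdb.gz")))
      hit <- file.path(dir, cand)[file.exists(file.path(dir, cand))]
      if (!length(hit))
        stop(sprintf("entry '%s' not found in mirror %s", id, dir))
      st <- read_structure_any(hit[[1L]])
      session$structures[[id]] <- st
      session_log(session, "fetch %s (%d atoms)", id, n_atoms(st))
    },
    show = {
      repr <- args[[1L]]
      nm <- opt$structure %||% last_structure_name(session)
      session$shown[[length(session$shown) + 1L]] <-
        list(structure = nm, repr = repr, selection = sel_of())
      session_log(session, "show %s on %s", repr, nm)
    },
    hide = {
      repr <- args[[1L]]
      was <- length(session$shown)
      session$shown <- Filter(function(a) a$repr != repr, session$shown)
      if (length(session$shown) == was)
        warning(sprintf("representation '%s' was not shown", repr))
      session_log(session, "hide %s", repr)
    },
    color = {
      what <- args[[1L]]
      nm <- opt$structure %||% last_structure_name(session)
      st <- session$structures[[nm]]
      cur <- session$colors[[nm]] %||%
        apply_scheme(st, NULL, "cpk")
      if (what %in% c("cpk", "group", "chain", "ss", "abego")) {
        idx <- as_atom_indices(st, sel_of())
        cur[idx, ] <- apply_scheme(st, sel_of(), what)[idx, ]
      } else {
        rgba <- parse_color(what)
        idx <- as_atom_indices(st, sel_of())
        cur[idx, ] <- matrix(rep(rgba, each = length(idx)), length(idx), 4L)
      }
      session$colors[[nm]] <- cur
      session_log(session, "color %s on %s", what, nm)
    },
    select = {
      nm <- args[[1L]]
      expr <- opt$selection %||% (if (length(args) > 1L)
        paste(args[-1L], collapse = " ") else stop("select needs an expression"))
      st <- session$structures[[opt$structure %||% last_structure_name(session)]]
      session$selections[[nm]] <- select_atoms(st, expr)
      session_log(session, "select %s = %s (%d atoms)", nm, expr,
                  length(session$selections[[nm]]))
    },
    set = {
      key <- args[[1L]]; val <- args[[2L]]
      num <- suppressWarnings(as.numeric(val))
      if (key %in% c("width", "height"))
        session[[key]] <- as.integer(num)
      else if (key %in% c("k_ambient", "k_diffuse", "k_specular", "shininess"))
        session$material[[key]] <- num
      else stop(sprintf("unknown setting '%s'", key))
      session_log(session, "set %s %s", key, val)
    },
    snapshot = {
      path <- args[[1L]]
      img <- session_render(session,
                            width = opt$width %||% session$width,
                            height = opt$height %||% session$height)
      write_png(img, path)
      session_log(session, "snapshot %s (%dx%d)", path, img$width, img$height)
    },
    movie = {
      outdir <- args[[1L]]
      if (is.null(session$trajectory)) stop("no trajectory loaded")
      nm <- opt$structure %||% last_structure_name(session)
      paths <- render_frames(session$structures[[nm]], session$trajectory,
                             outdir,
                             repr = opt$repr %||% "cartoon",
                             scheme = opt$scheme %||% "chain",
                             width = opt$width %||% session$width,
                             height = opt$height %||% session$height)
      session_log(session, "movie %s (%d frames)", outdir, length(paths))
    },
    stop(sprintf("unknown verb '%s'", verb)))
}

# Render everything currently shown (default: cartoon of every structure).
session_render <- function(session, width = 320L, height = 240L) {
  shown <- session$shown
  if (!length(shown))
    shown <- lapply(names(session$structures), function(nm)
      list(structure = nm, repr = "cartoon", selection = NULL))
  if (!length(shown)) stop("nothing to render")
  meshes <- lapply(shown, function(a) {
    st <- session$structures[[a$structure]]
    detail <- session$detail %||% lod_params(n_atoms(st))
    cols <- session$colors[[a$structure]] %||% apply_scheme(st, NULL, "cpk")
    build_representation(st, a$repr, a$selection, detail, cols)
  })
  mesh <- merge_meshes(meshes)
  camera <- auto_fit(mesh, width, height)
  rasterize(new_scene(mesh, material = session$material), camera)
}

#' Run a command script
#'
#' Executes commands line by line (`#` lines and blanks skipped) against a
#' fresh or given session. Deterministic: the same script and fixtures give
#' identical logs and identical output bytes.
#'
#' @param lines character vector of command lines, or a file path via
#'   `path`.
#' @param path script file path (alternative to `lines`).
#' @param session starting session.
#' @return final session.
#' @export
run_script <- function(lines = NULL, path = NULL, session = new_session()) {
  if (is.null(lines)) lines <- readLines(path)
  for (l in lines) {
    l <- trimws(l)
    if (!nzchar(l) || startsWith(l, "#")) next
    session <- execute(parse_command(l), session)
  }
  session
}

# extension-dispatched reader used by load/fetch
read_structure_any <- function(path) {
  base <- sub("\\.gz$", "", path)
  ext <- tolower(tools::file_ext(base))
  switch(ext,
    cif = build_structure(parse_mmcif(path = path)),
    json = build_structure(from_mmjson(path = path)),
    xml = build_structure(parse_pdbml(path = path)),
    pdb = , ent = parse_pdb(path = path),
    gro = parse_gro(path = path),
    mol2 = parse_mol2(path = path),
    mol = , sdf = , mdl = parse_mdl(path = path),
    trr = read_trr(path),
    xtc = read_xtc(path),
    ccp4 = , map = , mrc = read_ccp4(path),
    stop(sprintf("unrecognized file extension '.%s'", ext)))
}
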