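test_that("mmCIF grammar: tag/value pairs, loops, quoting, comments", {
  b <- parse_mmcif("data_TOY\n# a comment\n_cell.length_a 10.5\n")[[1]]
  expect_equal(b$name, "TOY")
  expect_equal(b$categories$cell$columns$length_a[[1]], 10.5)
  expect_equal(cif_nrows(b$categories$cell), 1L)

  b2 <- parse_mmcif("data_T\nloop_\n_a.x\n_a.y\n1 2\n3 4\n")[[1]]
  expect_identical(b2$categories$a$columns$x, list(1L, 3L))
  expect_identical(b2$categories$a$columns$y, list(2L, 4L))
  expect_equal(cif_nrows(b2$categories$a), 2L)

  b3 <- parse_mmcif("data_T\n_t.v 'C A'\n_t.w \"say 'hi'\"\n")[[1]]
  expect_identical(b3$categories$t$columns$v[[1]], "C A")
  expect_identical(b3$categories$t$columns$w[[1]], "say 'hi'")

  b4 <- parse_mmcif("data_T\n_t.v\n;line one\nline two\n;\n")[[1]]
  expect_identical(b4$categories$t$columns$v[[1]], "line one\nline two")
})

test_that("mmCIF typed values: numerics, zero-padded ids, nulls", {
  b <- parse_mmcif(
    "data_T\nloop_\n_s.a\n_s.b\n_s.c\n007 -3 1.5e2\n0 ? .\n")[[1]]
  s <- b$categories$s$columns
  expect_identical(s$a[[1]], "007")      # zero-padded id stays text
  expect_identical(s$a[[2]], 0L)
  expect_identical(s$b[[1]], -3L)
  expect_null(s$b[[2]])                  # unknown
  expect_identical(s$c[[1]], 150)
  expect_null(s$c[[2]])                  # inapplicable
})

test_that("mmCIF parse errors carry line numbers and reject dialect extras", {
  expect_error(parse_mmcif("_cell.length_a 1\n"), "data_")
  expect_error(parse_mmcif("data_T\nloop_\n_a.x\n_a.y\n1 2 3\n"),
               "line .*not a multiple")
  expect_error(parse_mmcif("data_T\nsave_foo\n_a.x 1\nsave_\n"), "save_")
  expect_error(parse_mmcif("global_\n_a.x 1\n"), "global_|data_")
})

test_that("write_mmcif round trip is the identity on the data model", {
  src <- paste0("data_T\n_one.a 1\n_one.b 'x y'\n_one.c ?\n",
                "loop_\n_two.p\n_two.q\n1.25 A\n-2 'b c'\n007 .\n")
  b <- parse_mmcif(src)
  rt <- parse_mmcif(write_mmcif(b))
  expect_true(isTRUE(cif_identical(rt, b)))
  # quoting and loop form
  txt <- write_mmcif(b)
  expect_match(txt, "'x y'", fixed = TRUE)
  expect_match(txt, "loop_", fixed = TRUE)
  # single-row category written in tag/value form, not loop
  expect_false(grepl("loop_\\s*\\n_one", txt))
  # null round trips as ?
  expect_null(parse_mmcif(txt)[[1]]$categories$one$columns$c[[1]])
})

test_that("values needing both quote styles fall back to text fields", {
  b <- cif_block("T", list(cif_category("x", list(
    v = list("has 'single' and \"double\""),
    w = list("multi\nline")))))
  rt <- parse_mmcif(write_mmcif(list(b)))
  expect_true(isTRUE(cif_identical(rt, list(b))))
})

test_that("to_mmjson maps blocks to column-major typed JSON", {
  b <- cif_block("TOY", list(
    cif_category("cell", list(length_a = list(10.5))),
    cif_category("atom_site", list(id = list(1L, 2L),
                                   type_symbol = list("C", NULL)))))
  js <- to_mmjson(list(b))
  expect_identical(
    js,
    paste0('{"data_TOY":{"cell":{"length_a":[10.5]},',
           '"atom_site":{"id":[1,2],"type_symbol":["C",null]}}}'))
  # "?" and "." both become null
  b2 <- parse_mmcif("data_T\nloop_\n_a.x\n_a.y\n? .\n")
  expect_identical(to_mmjson(b2), '{"data_T":{"a":{"x":[null],"y":[null]}}}')
  # empty block
  expect_identical(to_mmjson(cif_block("X")), '{"data_X":{}}')
})

test_that("from_mmjson inverts to_mmjson up to the ?/. collapse", {
  src <- paste0("data_T\n_one.a 1\n_one.b .\n",
                "loop_\n_two.p\n_two.q\n1.25 ?\n-2 x\n")
  b <- parse_mmcif(src)
  back <- from_mmjson(to_mmjson(b))
  # "." re-emerges as null == "?" on the model: compare after write
  expect_true(isTRUE(cif_identical(back, b)))
  expect_error(from_mmjson('{"data_A":{"c":{"x":[1],"y":[1,2]}}}'),
               "ragged.*'c'")
  expect_error(from_mmjson('{"nope":{}}'), "data_")
  got <- from_mmjson('{"data_A":{"c":{"x":[3],"y":[3.5]}}}')[[1]]
  expect_identical(got$categories$c$columns$x[[1]], 3L)
  expect_identical(got$categories$c$columns$y[[1]], 3.5)
})

test_that("codec round trips hold on property-generated random blocks", {
  set.seed(2024)
  for (rep in 1:60) {
    b <- random_datablock()
    # invariant: all columns equal length
    for (cc in b$categories)
      expect_true(length(unique(lengths(cc$columns))) <= 1L)
    rt1 <- parse_mmcif(write_mmcif(list(b)))
    ok1 <- cif_identical(rt1, list(b))
    if (!isTRUE(ok1)) fail(paste("mmCIF round trip:", ok1))
    js <- to_mmjson(list(b))
    expect_silent(jsonlite::fromJSON(js, simplifyVector = FALSE))
    rt2 <- from_mmjson(js)
    ok2 <- cif_identical(rt2, list(b))
    if (!isTRUE(ok2)) fail(paste("mmJSON round trip:", ok2))
    # nulls serialize as JSON null, never as bare ?/. tokens
    expect_false(grepl('"\\?"|"\\."', gsub('\\\\"', "", js)))
  }
})

test_that("numeric cells survive round trips to high precision", {
  set.seed(99)
  vals <- c(stats::rnorm(20, 0, 1e3), 1/3, pi, -2.718281828459045e-7)
  ints <- sample(-1e9:1e9, 10)
  b <- cif_block("N", list(cif_category("v", list(
    r = as.list(vals), i = as.list(c(ints, rep(0L, 13))))))) # equal lengths
  rt <- parse_mmcif(write_mmcif(list(b)))[[1]]
  got <- unlist(rt$categories$v$columns$r)
  expect_equal(got, vals, tolerance = 1e-12)
  expect_identical(unlist(rt$categories$v$columns$i)[1:10], ints)
  rt2 <- from_mmjson(to_mmjson(list(b)))[[1]]
  expect_equal(unlist(rt2$categories$v$columns$r), vals, tolerance = 1e-12)
})

test_that("PDBML parsing maps category elements and row cells", {
  t3 <- make_toy_mmcif()
  pb <- parse_pdbml(t3$pdbml)[[1]]
  expect_equal(pb$name, "TOY")
  as <- pb$categories$atom_site
  expect_equal(cif_nrows(as), 5L)
  expect_identical(as$columns$id[[1]], 1L)
  expect_identical(as$columns$Cartn_x[[1]], 11.104)
  # row 2 misses B_iso_or_equiv -> null cell
  expect_null(as$columns$B_iso_or_equiv[[2]])
  expect_identical(as$columns$B_iso_or_equiv[[1]], 10.5)
  expect_error(parse_pdbml("<unclosed"), ".")
})

test_that("cross-codec equality: mmCIF and PDBML give identical mmJSON", {
  t3 <- make_toy_mmcif()
  js_cif <- to_mmjson(parse_mmcif(t3$mmcif))
  js_xml <- to_mmjson(parse_pdbml(t3$pdbml))
  expect_identical(js_cif, js_xml)
  expect_identical(js_cif, t3$mmjson)
})

test_that("lite mmJSON keeps one trace atom per residue and whitelisted items", {
  st <- make_ideal_helix(6)  # 6 residues x 3 atoms, interior helix run
  blocks <- structure_to_blocks(st)
  js <- write_mmjson_lite(blocks)
  lb <- from_mmjson(js)[[1]]
  as <- lb$categories$atom_site
  expect_equal(cif_nrows(as), 6L)   # one CA per residue
  expect_true(all(unlist(as$columns$label_atom_id) == "CA"))
  allowed <- c("group_PDB", "label_atom_id", "label_comp_id", "label_asym_id",
               "auth_asym_id", "label_seq_id", "auth_seq_id",
               "Cartn_x", "Cartn_y", "Cartn_z", "pdbx_PDB_model_num")
  expect_true(all(names(as$columns) %in% allowed))
  # struct_conf passes through; everything else is dropped
  expect_true("struct_conf" %in% names(lb$categories))
  expect_true(all(names(lb$categories) %in%
                  c("atom_site", "struct_conf", "struct_sheet_range")))
  # strictly smaller than the full mmJSON
  expect_lt(nchar(js), nchar(to_mmjson(blocks)))
  # waters only -> zero rows
  wat <- cif_block("W", list(cif_category("atom_site", list(
    group_PDB = list("HETATM"), label_atom_id = list("O"),
    label_comp_id = list("HOH"), label_asym_id = list("A"),
    Cartn_x = list(0), Cartn_y = list(0), Cartn_z = list(0)))))
  expect_equal(cif_nrows(from_mmjson(write_mmjson_lite(list(wat)))[[1]]$
                           categories$atom_site), 0L)
  nob <- cif_block("N", list(cif_category("cell", list(a = list(1)))))
  expect_error(write_mmjson_lite(list(nob)), "atom_site")
})

test_that("gzip input is detected by magic bytes for all text codecs", {
  t3 <- make_toy_mmcif()
  td <- withr::local_tempdir()
  gzf <- file.path(td, "toy.cif.gz")
  con <- gzfile(gzf, "wb"); writeBin(charToRaw(t3$mmcif), con); close(con)
  expect_true(isTRUE(cif_identical(parse_mmcif(path = gzf),
                                   parse_mmcif(t3$mmcif))))
  gj <- file.path(td, "toy.json.gz")
  con <- gzfile(gj, "wb"); writeBin(charToRaw(t3$mmjson), con); close(con)
  expect_identical(to_mmjson(from_mmjson(path = gj)), t3$mmjson)
})

test_that("compare_compressed_sizes reports per-entry and mean reductions", {
  td <- withr::local_tempdir()
  t3 <- make_toy_mmcif()
  for (e in c("aaa", "bbb")) {
    writeLines(t3$mmcif, file.path(td, paste0(e, ".cif")))
    writeLines(t3$pdbml, file.path(td, paste0(e, ".xml")))
  }
  tab <- compare_compressed_sizes(td)
  expect_equal(nrow(tab), 2L)
  # identical entries -> identical reductions; mean equals the single value
  expect_equal(tab$red_vs_mmcif[1], tab$red_vs_mmcif[2])
  expect_equal(attr(tab, "mean_vs_mmcif"), tab$red_vs_mmcif[1])
  expect_equal(tab$red_vs_pdbml,
               100 * (1 - tab$gz_mmjson / tab$gz_pdbml))
  # empty corpus
  empty <- compare_compressed_sizes(withr::local_tempdir())
  expect_equal(nrow(empty), 0L)
  expect_true(is.na(attr(empty, "mean_vs_mmcif")))
  # unreadable entry skipped with a warning but counted
  writeLines("not cif at all", file.path(td, "bad.cif"))
  writeLines(t3$pdbml, file.path(td, "bad.xml"))
  expect_warning(tab2 <- compare_compressed_sizes(td), "skipped")
  expect_equal(nrow(tab2), 2L)
  expect_equal(attr(tab2, "skipped"), "bad")
})
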