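test_that("parse_command handles the grammar and function-call forms", {
  c1 <- parse_command("molmil.loadPDB('1crn')")
  expect_equal(c1$verb, "fetch")
  expect_equal(c1$args, "1crn")
  c1b <- parse_command("molmil.loadPDBlite('3j3q')")
  expect_equal(c1b$verb, "fetch")
  expect_true(isTRUE(c1b$options$lite))
  c2 <- parse_command("color red, chain A")
  expect_equal(c2$verb, "color")
  expect_equal(c2$args, "red")
  expect_equal(c2$options$selection, "chain A")
  c3 <- parse_command("snapshot out.png, width=640, height=480")
  expect_equal(c3$options$width, 640L)
  c4 <- parse_command("load 'my file.cif'")
  expect_equal(c4$args, "my file.cif")
  expect_error(parse_command("frobnicate x"), "unknown verb.*load")
  expect_error(parse_command("show 'cartoon"), "quot.*position|position")
})

test_that("format_command round trips the command model", {
  cmds <- list(
    parse_command("fetch toy"),
    parse_command("color red, chain A"),
    parse_command("show cartoon, resi 1-10"),
    parse_command("snapshot 'a b.png', width=320"),
    parse_command("set shininess 16"))
  for (cmd in cmds) {
    back <- parse_command(format_command(cmd))
    expect_equal(back, cmd)
  }
})

test_that("URL fragments split on semicolons and percent-decode", {
  cmds <- parse_url_fragment(
    "http://example.org/viewer#molmil.loadPDB('1crn')")
  expect_length(cmds, 1L)
  expect_equal(cmds[[1]]$verb, "fetch")
  expect_equal(cmds[[1]]$args, "1crn")
  two <- parse_url_fragment("x#fetch toy;show cartoon")
  expect_length(two, 2L)
  expect_equal(vapply(two, `[[`, "", "verb"), c("fetch", "show"))
  dec <- parse_url_fragment("x#load a%20b.cif")
  expect_equal(dec[[1]]$args, "a b.cif")
  expect_length(parse_url_fragment("http://example.org/nofragment"), 0L)
  expect_length(parse_url_fragment("x#"), 0L)
})

test_that("execute: fetch/show/color/snapshot end-to-end on the packaged fixture", {
  td <- withr::local_tempdir()
  png <- file.path(td, "out.png")
  s <- new_session()
  s <- execute(parse_command("fetch toy"), s)
  s <- execute(parse_command("show cartoon"), s)
  s <- execute(parse_command("color chain"), s)
  s <- execute(parse_command(sprintf("snapshot %s, width=96, height=72", png)), s)
  expect_length(s$log, 4L)
  expect_true(file.exists(png))
  a <- read_png(png)
  expect_equal(dim(a)[1:2], c(72L, 96L))
  cov <- mean(a[, , 1] < 250 | a[, , 2] < 250 | a[, , 3] < 250)
  expect_gt(cov, 0.01)
})

test_that("execute is deterministic: same script, same log, same bytes", {
  td <- withr::local_tempdir()
  run_once <- function(stem) {
    png <- file.path(td, paste0(stem, ".png"))
    s <- run_script(c("fetch toy", "show cartoon", "color chain",
                      sprintf("snapshot %s, width=96, height=72", png)))
    list(log = sub(png, "PNG", s$log, fixed = TRUE),
         bytes = readBin(png, "raw", file.size(png)))
  }
  a <- run_once("a"); b <- run_once("b")
  expect_identical(a$log, b$log)
  expect_identical(a$bytes, b$bytes)
})

test_that("load dispatches by extension; hide of unshown warns as no-op", {
  td <- withr::local_tempdir()
  t3 <- make_toy_mmcif()
  cif <- file.path(td, "t.cif"); writeLines(t3$mmcif, cif)
  s <- execute(parse_command(paste("load", cif)))
  expect_length(s$structures, 1L)
  expect_equal(n_atoms(s$structures$t), 5L)
  s2 <- execute(parse_command("show vdw"), s)
  expect_warning(s3 <- execute(parse_command("hide cartoon"), s2), "not shown")
  expect_length(s3$shown, 1L)  # vdw still shown
  s4 <- suppressWarnings(execute(parse_command("hide vdw"), s3))
  expect_length(s4$shown, 0L)
  expect_error(execute(parse_command("load nope.xyz"), s), "no such file")
})

test_that("select stores named selections; set updates settings", {
  s <- execute(parse_command("fetch toy"))
  s <- execute(parse_command("select core, resi 3-6"), s)
  expect_length(s$selections$core, 4 * 3)   # 4 residues x 3 backbone atoms
  s <- execute(parse_command("set shininess 8"), s)
  expect_equal(s$material$shininess, 8)
  expect_error(execute(parse_command("set nonsense 1"), s), "unknown setting")
  expect_error(execute(parse_command("fetch missing_entry"), s), "not found")
  bad <- new_session(fetch_dir = "/nonexistent/dir")
  expect_error(execute(parse_command("fetch toy"), bad), "fetch source|not found")
})

test_that("movie renders trajectory frames through the session", {
  td <- withr::local_tempdir()
  fx <- make_random_walk_trajectory(n_atoms = 48L, n_frames = 2L, seed = 5)
  trr <- file.path(td, "t.trr")
  writeBin(fx$trr, trr)
  s <- new_session()
  s <- execute(parse_command("fetch toy"), s)
  s <- execute(parse_command(paste("load", trr)), s)
  expect_equal(length(s$trajectory$frames), 2L)
  out <- file.path(td, "frames")
  s <- execute(parse_command(
    sprintf("movie %s, repr=tube, width=64, height=48", out)), s)
  expect_length(list.files(out, pattern = "frame_.*png"), 2L)
})
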