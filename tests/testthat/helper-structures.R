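# Shared in-code fixtures for the test suite.

# a tiny two-chain structure with hetero water, built straight from tables
tiny_structure <- function() {
  atoms <- data.frame(
    serial = 1:7,
    name = c("N", "CA", "C", "CA", "CA", "O", "CA"),
    element = c("N", "C", "C", "C", "C", "O", "C"),
    alt_loc = "", is_hetero = c(rep(FALSE, 5), TRUE, FALSE),
    comp_id = c("ALA", "ALA", "ALA", "GLY", "GLY", "HOH", "ALA"),
    seq_id = c(10L, 10L, 10L, 11L, 12L, 101L, 1L),
    ins_code = "",
    asym_id = c(rep("A", 6), "B"),
    auth_asym_id = c(rep("A", 6), "B"),
    occupancy = 1, b_factor = 0, stringsAsFactors = FALSE)
  co <- rbind(c(0, 0, 0), c(1.46, 0, 0), c(2.0, 1.4, 0),
              c(4.5, 1.5, 0), c(8.0, 1.5, 0), c(20, 20, 20), c(30, 0, 0))
  new_structure(atoms, list(co), entry_id = "TINY")
}

# a random cloud of carbons for bond/selection property tests
random_carbon_structure <- function(n, spread = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  atoms <- data.frame(
    serial = seq_len(n), name = "C", element = "C", alt_loc = "",
    is_hetero = FALSE, comp_id = "LIG", seq_id = seq_len(n), ins_code = "",
    asym_id = "A", auth_asym_id = "A", occupancy = 1, b_factor = 0,
    stringsAsFactors = FALSE)
  co <- matrix(runif(n * 3, 0, spread), ncol = 3)
  new_structure(atoms, list(co), entry_id = "RAND")
}

expect_valid_mesh <- function(mesh) {
  expect_true(isTRUE(mesh_validate(mesh)))
}

# every edge of a closed surface must be shared by exactly two triangles
edge_share_counts <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(table(key))
}

# number of connected components of a mesh (union-find over triangle edges)
mesh_components <- function(mesh) {
  n <- nrow(mesh$positions)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  tr <- mesh$triangles
  for (i in seq_len(nrow(tr))) {
    a <- find(tr[i, 1]); b <- find(tr[i, 2]); c <- find(tr[i, 3])
    parent[b] <- a; parent[c] <- a
  }
  length(unique(vapply(seq_len(n), find, 0L)))
}
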