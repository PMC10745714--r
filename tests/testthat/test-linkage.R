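# Oligomer assembly: atom bookkeeping, torsion presets, the split-plane
# partition, ring integrity.

test_that("assembly conserves atoms: 3 atoms lost per linkage", {
  tri <- assemble_oligomer(tri_topology(),
                           classes = c(first = "trans", second = "trans"))
  expect_identical(n_atoms(tri), 24L + 30L + 30L - 2L * 3L)
  tm_topo <- oligomer_topology(
    residues = data.frame(tag = c("M", "M'", "M''"),
                          template = rep("alpha-D-Man", 3),
                          stringsAsFactors = FALSE),
    linkages = data.frame(child = c("M'", "M''"), parent = c("M", "M"),
                          parent_pos = c(3L, 6L), slot = c("first", "second"),
                          stringsAsFactors = FALSE))
  tm <- assemble_oligomer(tm_topo, classes = c(first = "cis", second = "cis"))
  expect_identical(n_atoms(tm), 3L * 24L - 2L * 3L)
})

test_that("a single residue with no linkage is the bare template", {
  topo <- oligomer_topology(
    residues = data.frame(tag = "X", template = "alpha-D-Man",
                          stringsAsFactors = FALSE), linkages = NULL)
  s <- assemble_oligomer(topo)
  expect_identical(coords(s), coords(build_template("alpha-D-Man")))
})

test_that("1->4 linkages consume the OH4 sites of the parents", {
  tri <- assemble_oligomer(tri_topology(),
                           classes = c(first = "trans", second = "trans"))
  s <- tri$sites
  expect_false(any(s$residue == "G'" & s$label == "OH4"))
  expect_false(any(s$residue == "G" & s$label == "OH4"))
  expect_true(any(s$residue == "G'" & s$label == "B4"))
  # children lose their anomeric hydroxyl; the reducing end keeps it
  expect_false(any(s$residue %in% c("M", "G'") & s$label == "OH1"))
  expect_true(any(s$residue == "G" & s$label == "OH1"))
})

test_that("class presets are exact and idempotent", {
  di <- assemble_oligomer(man_glcnac_topology(), classes = c(link = "trans"))
  expect_equal(unname(measure_linkage(di, "link")[c("phi", "psi")]),
               c(50, 120), tolerance = 1e-6)
  di_cis <- set_linkage_conformation(di, "link", "cis")
  expect_equal(unname(measure_linkage(di_cis, "link")[c("phi", "psi")]),
               c(-80, 90), tolerance = 1e-6)
  again <- set_linkage_conformation(di_cis, "link", "cis")
  expect_lt(max(abs(coords(again) - coords(di_cis))), 1e-6)
  expect_error(set_linkage_conformation(di, "link", "gauche"),
               "parameter error")
})

test_that("ring torsions survive linkage-torsion changes", {
  di <- assemble_oligomer(man_glcnac_topology(), classes = c(link = "trans"))
  ring <- vapply(c("C1", "C2", "C3", "C4", "C5", "O5"),
                 function(n) atom_index(di, "M", n), 1L)
  tors <- function(s) vapply(1:6, function(k) {
    q <- ring[c(k, k %% 6 + 1, (k + 1) %% 6 + 1, (k + 2) %% 6 + 1)]
    measure_dihedral(s, q[1], q[2], q[3], q[4])
  }, 0)
  before <- tors(di)
  after <- tors(set_linkage_conformation(di, "link", "cis"))
  expect_equal(after, before, tolerance = 1e-6)
})

test_that("topology errors are caught", {
  res <- data.frame(tag = c("A", "B"), template = rep("alpha-D-Man", 2),
                    stringsAsFactors = FALSE)
  expect_error(oligomer_topology(res, data.frame(
    child = c("A", "A"), parent = c("B", "B"), parent_pos = c(4L, 3L),
    slot = c("s1", "s2"), stringsAsFactors = FALSE)),
    "child of two linkages")
  expect_error(oligomer_topology(res, data.frame(
    child = c("A", "B"), parent = c("B", "A"), parent_pos = c(4L, 4L),
    slot = c("s1", "s2"), stringsAsFactors = FALSE)), "cyclic")
  expect_error(oligomer_topology(res, data.frame(
    child = "A", parent = "C", parent_pos = 4L, slot = "s1",
    stringsAsFactors = FALSE)), "unknown residue")
})

test_that("split-plane partition reproduces the documented face assignment", {
  tri <- assemble_oligomer(tri_topology(),
                           classes = c(first = "trans", second = "trans"))
  ox <- c(atom_index(tri, "M", "O5"), atom_index(tri, "G'", "O5"),
          atom_index(tri, "G", "O5"))
  p <- partition_upper_lower(tri, ox)
  reg <- function(res, lab) p$region[p$residue == res & p$label == lab]
  # hydroxymethyl groups upper
  expect_identical(reg("M", "OH6"), "upper")
  expect_identical(reg("G'", "OH6"), "upper")
  expect_identical(reg("G", "OH6"), "upper")
  # C2/C3 substituents of the GlcNAc rings lower
  expect_identical(reg("G", "OH3"), "lower")
  expect_identical(reg("G'", "OH3"), "lower")
  expect_identical(reg("G", "NHCO"), "lower")
  expect_identical(reg("G'", "NHCO"), "lower")
  # every site assigned exactly one region
  expect_true(all(p$region %in% c("upper", "lower")))
  expect_identical(nrow(p), nrow(tri$sites))
})

test_that("partition is invariant under rigid motion", {
  set.seed(7)
  tri <- assemble_oligomer(tri_topology(),
                           classes = c(first = "trans", second = "cis"))
  ox <- c(atom_index(tri, "M", "O5"), atom_index(tri, "G'", "O5"),
          atom_index(tri, "G", "O5"))
  ref <- partition_upper_lower(tri, ox)
  for (k in 1:5) {
    s2 <- transform_structure(tri, glycotree:::random_rotation(),
                              rnorm(3, sd = 25))
    expect_identical(partition_upper_lower(s2, ox)$region, ref$region)
  }
})
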