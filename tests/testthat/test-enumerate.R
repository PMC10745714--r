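# The three-step tree: direction expansion, catalog enumeration,
# brute-force equivalence, determinism.

test_that("toy catalog: two reversible non-conflicting chains give 2x2 variants", {
  res <- enumerate_conformers(toy_catalog(), build_structures = FALSE)
  expect_identical(total_conformers(res), 4L)
  dirs <- t(vapply(res$conformers, function(c) c$directions, c(u1 = "", u2 = "")))
  expect_identical(nrow(unique(as.data.frame(dirs))), 4L)
  # lexicographic order: first unit most significant
  expect_identical(unname(dirs[, "u1"]), c("fwd", "fwd", "rev", "rev"))
})

test_that("direction expansion matches the stated group cardinalities", {
  cat_tri <- builtin_catalog("nag2man-trisaccharide")
  by_label <- function(l) cat_tri$groups[[which(vapply(cat_tri$groups,
                                                       function(g) g$label, "") == l)]]
  expect_identical(nrow(expand_directions(by_label("K"), cat_tri)), 8L)
  expect_identical(nrow(expand_directions(by_label("O"), cat_tri)), 4L)
  expect_identical(nrow(expand_directions(by_label("B"), cat_tri)), 1L)
  # a group with no reversible unit has exactly one variant
  cat_di <- builtin_catalog("nag2-disaccharide")
  expect_identical(nrow(expand_directions(cat_di$groups[[1]], cat_di)), 1L)
})

test_that("built-in trisaccharide catalogs reproduce the published tallies", {
  counts <- function(name) {
    r <- suppressWarnings(enumerate_conformers(builtin_catalog(name),
                                               build_structures = FALSE))
    r$counts
  }
  tt <- counts("trisaccharide-trans-trans1")
  expect_identical(sum(tt$count), 4L)
  expect_identical(tt$count[tt$group == "A"], 3L)
  expect_identical(tt$count[tt$group == "B"], 1L)
  tc <- counts("trisaccharide-trans-cis1")
  expect_identical(sum(tc$count), 12L)
  expect_identical(nrow(tc), 8L)
  expect_identical(tc$count[tc$group %in% c("C", "D", "E", "F")],
                   rep(1L, 4))
  expect_identical(tc$count[tc$group %in% c("G", "H", "I", "J")],
                   rep(2L, 4))
  cc <- counts("trisaccharide-cis-cis1")
  expect_identical(cc$count[cc$group == "K"], 8L)
  expect_identical(cc$count[cc$group == "O"], 4L)
  expect_identical(sum(cc$count), 36L)
  ct <- counts("trisaccharide-cis-trans1")
  expect_identical(ct$count[ct$group %in% c("P", "Q", "R", "S")],
                   rep(2L, 4))
  expect_identical(ct$count[ct$group == "T"], 1L)
  expect_identical(sum(ct$count), 9L)
})

test_that("trimannose catalog reproduces the published per-group counts", {
  r <- suppressWarnings(enumerate_conformers(builtin_catalog("trimannose"),
                                             build_structures = FALSE))
  cn <- stats::setNames(r$counts$count, r$counts$group)
  expect_identical(cn[["A"]], 4L)
  expect_identical(cn[["B"]], 2L)
  expect_identical(cn[["C"]], 4L)
  expect_identical(cn[["D"]], 4L)
  expect_identical(cn[["E"]], 2L)
  expect_identical(cn[["G"]], 1L)
  expect_identical(cn[["J"]], 2L)
  expect_identical(total_conformers(r), 27L)
})

test_that("enumeration equals brute-force direction expansion on all catalogs", {
  for (nm in c("nag2man-trisaccharide", "trimannose", "nag2-disaccharide")) {
    cat_ <- builtin_catalog(nm)
    res <- suppressWarnings(enumerate_conformers(cat_,
                                                 build_structures = FALSE))
    for (g in cat_$groups) {
      sk <- assemble_oligomer(cat_$topology, classes = g$classes)
      expect_identical(res$counts$count[res$counts$group == g$label],
                       brute_force_group_count(g, cat_, sk),
                       info = paste(nm, g$label))
    }
  }
})

test_that("enumeration is deterministic with unique provenance", {
  r1 <- suppressWarnings(enumerate_conformers(
    builtin_catalog("trisaccharide-trans-trans1")))
  r2 <- suppressWarnings(enumerate_conformers(
    builtin_catalog("trisaccharide-trans-trans1")))
  ids <- vapply(r1$conformers, function(c) c$id, "")
  expect_identical(ids, vapply(r2$conformers, function(c) c$id, ""))
  expect_false(anyDuplicated(ids) > 0)
  expect_identical(coords(r1$conformers[[2]]$structure),
                   coords(r2$conformers[[2]]$structure))
  # emitted conformers carry built structures with solved chains
  expect_identical(n_atoms(r1$conformers[[1]]$structure), 78L)
  # within a group, no two conformers share a realized hydrogen-bond set
  byg <- split(r1$conformers, vapply(r1$conformers, function(c) c$group, ""))
  for (g in byg) {
    keys <- vapply(g, function(c)
      paste(sort(sprintf("%s%s>%s%s", c$realized$donor,
                         c$realized$donor_residue, c$realized$acceptor,
                         c$realized$acceptor_residue)), collapse = "|"), "")
    expect_false(anyDuplicated(keys) > 0)
  }
})

test_that("fragile trimannose groups carry their warning flag", {
  w <- capture_warnings(
    enumerate_conformers(builtin_catalog("trimannose"),
                         build_structures = FALSE))
  # both fragile cis-cis groups (C and D) are flagged, nothing else
  expect_identical(sum(grepl("hydroxymethyl flexibility", w)), 2L)
})

test_that("invalid catalogs are rejected with the offending site named", {
  bad <- toy_catalog()
  bad$groups[[1]]$units[[2]]$fwd <- "OH2->OH6"  # OH2 donates in both units
  issues <- validate_catalog(bad)
  expect_true(any(grepl("double-donation.*OH2", issues$issue)))
  expect_error(enumerate_conformers(bad, build_structures = FALSE),
               "catalog error")
})
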