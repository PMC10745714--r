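# Geometry kernel: z-matrix construction, dihedral measurement and
# setting, rigid-motion invariance.

simple_zmatrix <- function() {
  data.frame(
    element = c("C", "C", "C", "C"),
    name = c("A1", "A2", "A3", "A4"),
    residue = "X",
    bond_ref = c(NA, 1L, 2L, 3L),
    length = c(NA, 1.5, 1.5, 1.5),
    angle_ref = c(NA, NA, 1L, 2L),
    angle = c(NA, NA, 109.47, 109.47),
    torsion_ref = c(NA, NA, NA, 1L),
    torsion = c(NA, NA, NA, 0),
    stringsAsFactors = FALSE)
}

test_that("z-matrix construction round-trips bonds, angles and torsions", {
  zm <- simple_zmatrix()
  zm$length[2] <- 1.0
  s <- zmatrix_to_cartesian(zm)
  expect_equal(measure_distance(s, 1, 2), 1.0, tolerance = 1e-9)
  expect_equal(measure_angle(s, 1, 2, 3), 109.47, tolerance = 1e-6)
  expect_equal(measure_dihedral(s, 1, 2, 3, 4), 0, tolerance = 1e-6)
  for (tor in c(-135.2, -60, 57.3, 180)) {
    zm$torsion[4] <- tor
    s <- zmatrix_to_cartesian(zm)
    expect_equal(measure_dihedral(s, 1, 2, 3, 4), tor, tolerance = 1e-6)
  }
})

test_that("z-matrix errors: dangling references and degenerate frames", {
  zm <- simple_zmatrix()
  zm$bond_ref[3] <- 5L
  expect_error(zmatrix_to_cartesian(zm), "dangling")
  zm <- simple_zmatrix()
  zm$angle[4] <- 180
  expect_error(zmatrix_to_cartesian(zm), "degenerate|angle out")
})

test_that("a full mannose template z-matrix yields 24 atoms (C6H12O6)", {
  tpl <- build_template("alpha-D-Man")
  zm <- cartesian_to_zmatrix(tpl)
  s <- zmatrix_to_cartesian(zm)
  expect_identical(n_atoms(s), 24L)
  expect_identical(sort(table(s$atoms$element)),
                   sort(table(tpl$atoms$element)))
})

test_that("cartesian -> internal -> cartesian preserves pairwise distances", {
  tpl <- build_template("beta-D-GlcNAc")
  s2 <- zmatrix_to_cartesian(cartesian_to_zmatrix(tpl))
  d1 <- as.matrix(dist(coords(tpl)))
  d2 <- as.matrix(dist(coords(s2)))
  expect_lt(max(abs(d1 - d2)), 1e-6)
})

test_that("measure_dihedral handles the canonical planar and chiral cases", {
  mk <- function(pts) glyco_structure(data.frame(
    element = "C", name = paste0("A", seq_len(nrow(pts))), residue = "X",
    x = pts[, 1], y = pts[, 2], z = pts[, 3], stringsAsFactors = FALSE))
  cis <- mk(rbind(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)))
  expect_equal(measure_dihedral(cis, 1, 2, 3, 4), 0, tolerance = 1e-9)
  trans <- mk(rbind(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(-1, 0, 0)))
  expect_equal(abs(measure_dihedral(trans, 1, 2, 3, 4)), 180,
               tolerance = 1e-9)
  # hand-evaluated cross-product formula for this corner geometry: |90|
  corner <- mk(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)))
  expect_equal(abs(measure_dihedral(corner, 1, 2, 3, 4)), 90,
               tolerance = 1e-9)
  # collinear frame
  lin <- mk(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)))
  expect_error(measure_dihedral(lin, 1, 2, 3, 4), "degenerate")
})

test_that("measure_dihedral is invariant under rigid motions", {
  set.seed(42)
  tpl <- build_template("alpha-D-Man")
  i <- function(n) atom_index(tpl, "X", n)
  q <- c(i("O5"), i("C1"), i("C2"), i("C3"))
  ref <- measure_dihedral(tpl, q[1], q[2], q[3], q[4])
  for (k in 1:8) {
    rot <- glycotree:::random_rotation()
    s2 <- transform_structure(tpl, rot, rnorm(3, sd = 10))
    expect_equal(measure_dihedral(s2, q[1], q[2], q[3], q[4]), ref,
                 tolerance = 1e-9)
  }
})

test_that("set_dihedral round-trips, restores coordinates, rejects rings", {
  tpl <- build_template("alpha-D-Man")
  i <- function(n) atom_index(tpl, "X", n)
  q <- c(i("C1"), i("C2"), i("O2"), i("HO2"))
  orig <- measure_dihedral(tpl, q[1], q[2], q[3], q[4])
  for (target in c(0, 50, -171.25)) {
    s2 <- set_dihedral(tpl, q[1], q[2], q[3], q[4], target)
    expect_equal(measure_dihedral(s2, q[1], q[2], q[3], q[4]), target,
                 tolerance = 1e-6)
    # only the hydrogen moved; bond lengths unchanged
    expect_equal(measure_distance(s2, q[3], q[4]),
                 measure_distance(tpl, q[3], q[4]), tolerance = 1e-9)
    back <- set_dihedral(s2, q[1], q[2], q[3], q[4], orig)
    expect_lt(max(abs(coords(back) - coords(tpl))), 1e-6)
  }
  # ring bond C1-C2 cannot be rotated
  expect_error(set_dihedral(tpl, i("O5"), i("C1"), i("C2"), i("C3"), 10),
               "not-rotatable")
})
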