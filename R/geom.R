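# Cartesian / internal-coordinate geometry kernel.
#
# Angles are degrees throughout; torsions live in (-180, 180] with the IUPAC
# sign convention (looking from b to c, a clockwise rotation of d is positive;
# cis = 0).  Distances are Angstrom.

DEG <- pi / 180

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("degenerate-frame error: zero-length vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Wrap an angle into (-180, 180]
#' @param x angle in degrees
#' @return wrapped angle
#' @keywords internal
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  ifelse(y <= -180, y + 360, y)
}

#' Create a molecular structure
#'
#' A `glyco_structure` holds an ordered atom table (element, residue-local
#' name, residue tag, Cartesian position in Angstrom) and a bond list.
#' Functional-group site annotations (used by the hydrogen-bond machinery)
#' travel with the structure as the `sites` attribute.
#'
#' @param atoms data.frame with columns `element`, `name`, `residue`,
#'   `x`, `y`, `z`
#' @param bonds two-column integer matrix of 1-based atom indices
#' @param sites optional site table (see [template_sites()])
#' @return an object of class `glyco_structure`
#' @export
glyco_structure <- function(atoms, bonds = matrix(integer(0), ncol = 2),
                            sites = NULL) {
  stopifnot(is.data.frame(atoms),
            all(c("element", "name", "residue", "x", "y", "z") %in% names(atoms)))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom position", call. = FALSE)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) && (min(bonds) < 1 || max(bonds) > nrow(atoms)))
    stop("bond index out of range", call. = FALSE)
  structure(list(atoms = atoms, bonds = bonds, sites = sites),
            class = "glyco_structure")
}

#' @export
print.glyco_structure <- function(x, ...) {
  cat(sprintf("<glyco_structure: %d atoms, %d bonds, residues: %s>\n",
              nrow(x$atoms), nrow(x$bonds),
              paste(unique(x$atoms$residue), collapse = " ")))
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure a `glyco_structure`
#' @return integer atom count
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' Coordinate matrix of a structure
#' @param structure a `glyco_structure`
#' @return numeric matrix with one row per atom (x, y, z)
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

set_coords <- function(structure, xyz) {
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

#' Find an atom index by residue tag and atom name
#' @param structure a `glyco_structure`
#' @param residue residue tag (e.g. `"M"`, `"G'"`)
#' @param name residue-local atom name (e.g. `"C1"`, `"O5"`)
#' @return integer atom index
#' @export
atom_index <- function(structure, residue, name) {
  i <- which(structure$atoms$residue == residue & structure$atoms$name == name)
  if (length(i) != 1L)
    stop(sprintf("atom %s/%s: found %d matches", residue, name, length(i)),
         call. = FALSE)
  i
}

#' Measure an interatomic distance
#' @param structure a `glyco_structure`
#' @param a,b atom indices
#' @return distance in Angstrom
#' @export
measure_distance <- function(structure, a, b) {
  xyz <- coords(structure)
  vnorm(xyz[a, ] - xyz[b, ])
}

#' Measure a bond angle
#' @param structure a `glyco_structure`
#' @param a,b,c atom indices; the angle is at `b`
#' @return angle in degrees, in (0, 180)
#' @export
measure_angle <- function(structure, a, b, c) {
  xyz <- coords(structure)
  u <- unitv(xyz[a, ] - xyz[b, ])
  v <- unitv(xyz[c, ] - xyz[b, ])
  acos(max(-1, min(1, sum(u * v)))) / DEG
}

dihedral_points <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10)
    stop("degenerate-frame error: collinear atoms in dihedral", call. = FALSE)
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrap_angle(atan2(y, x) / DEG)
}

#' Measure a dihedral angle
#'
#' Sign follows the IUPAC convention: looking along b -> c, a clockwise
#' rotation of d relative to a is positive; a planar cis arrangement is 0
#' and trans is 180.
#'
#' @param structure a `glyco_structure`
#' @param a,b,c,d four distinct atom indices
#' @return angle in degrees, in (-180, 180]
#' @export
measure_dihedral <- function(structure, a, b, c, d) {
  if (length(unique(c(a, b, c, d))) != 4L)
    stop("dihedral needs four distinct atoms", call. = FALSE)
  xyz <- coords(structure)
  dihedral_points(xyz[a, ], xyz[b, ], xyz[c, ], xyz[d, ])
}

rodrigues <- function(v, axis, angle_deg) {
  k <- unitv(axis)
  th <- angle_deg * DEG
  v * cos(th) + cross3(k, v) * sin(th) + k * sum(k * v) * (1 - cos(th))
}

# Atoms reachable from `from` when the edge (cut_a, cut_b) is removed.
component_after_cut <- function(structure, cut_a, cut_b, from) {
  n <- n_atoms(structure)
  adj <- vector("list", n)
  for (i in seq_len(nrow(structure$bonds))) {
    a <- structure$bonds[i, 1]; b <- structure$bonds[i, 2]
    if ((a == cut_a && b == cut_b) || (a == cut_b && b == cut_a)) next
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(n)
  queue <- from
  seen[from] <- TRUE
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  which(seen)
}

#' Set a dihedral angle by rotating about the b-c bond
#'
#' Rotates exactly the atoms on d's side of the b-c cut so that the
#' dihedral a-b-c-d equals `target`.  Bond lengths and angles are
#' unchanged.  Fails if b-c lies in a ring (the cut does not separate the
#' bond graph).
#'
#' @param structure a `glyco_structure`
#' @param a,b,c,d atom indices defining the dihedral
#' @param target target angle in degrees
#' @return the modified structure
#' @export
set_dihedral <- function(structure, a, b, c, d, target) {
  side <- component_after_cut(structure, b, c, d)
  if (b %in% side)
    stop("not-rotatable error: bond lies in a ring", call. = FALSE)
  cur <- measure_dihedral(structure, a, b, c, d)
  delta <- wrap_angle(target - cur)
  xyz <- coords(structure)
  axis <- xyz[c, ] - xyz[b, ]
  origin <- xyz[b, ]
  move <- setdiff(side, c(b, c))
  for (i in move)
    xyz[i, ] <- origin + rodrigues(xyz[i, ] - origin, axis, -delta)
  set_coords(structure, xyz)
}

#' Build Cartesian coordinates from internal-coordinate rows
#'
#' Each row places one atom: the first row needs no references, the second
#' a bond reference, the third bond + angle references, and subsequent rows
#' bond + angle + torsion references to already-placed atoms (the NeRF
#' construction).
#'
#' @param rows data.frame with columns `element`, `name`, `residue`,
#'   `bond_ref`, `length`, `angle_ref`, `angle`, `torsion_ref`, `torsion`
#'   (references are row indices of earlier atoms; `NA` where unused)
#' @param bonds optional explicit bond matrix; by default each atom is
#'   bonded to its `bond_ref`
#' @return a `glyco_structure`
#' @export
zmatrix_to_cartesian <- function(rows, bonds = NULL) {
  n <- nrow(rows)
  if (n < 1) stop("empty z-matrix", call. = FALSE)
  xyz <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    r <- rows[i, ]
    if (i == 1) {
      xyz[i, ] <- c(0, 0, 0)
    } else {
      j <- r$bond_ref
      if (is.na(j) || j >= i || j < 1)
        stop(sprintf("dangling reference in z-matrix row %d", i), call. = FALSE)
      if (!is.finite(r$length) || r$length <= 0)
        stop(sprintf("bad bond length in z-matrix row %d", i), call. = FALSE)
      if (i == 2) {
        xyz[i, ] <- xyz[j, ] + c(r$length, 0, 0)
      } else {
        k <- r$angle_ref
        if (is.na(k) || k >= i || k < 1 || k == j)
          stop(sprintf("dangling reference in z-matrix row %d", i), call. = FALSE)
        if (!is.finite(r$angle) || r$angle <= 0 || r$angle >= 180)
          stop(sprintf("degenerate-frame error: angle out of (0,180) in row %d", i),
               call. = FALSE)
        if (i == 3) {
          # place in the xy-plane relative to j, k
          u <- unitv(xyz[k, ] - xyz[j, ])
          # any perpendicular in-plane direction
          perp <- c(-u[2], u[1], 0)
          if (vnorm(perp) < 1e-8) perp <- c(0, 1, 0)
          perp <- unitv(perp)
          th <- r$angle * DEG
          xyz[i, ] <- xyz[j, ] + r$length * (cos(th) * u + sin(th) * perp)
        } else {
          l <- r$torsion_ref
          if (is.na(l) || l >= i || l < 1 || l %in% c(j, k))
            stop(sprintf("dangling reference in z-matrix row %d", i), call. = FALSE)
          xyz[i, ] <- nerf_place(xyz[l, ], xyz[k, ], xyz[j, ],
                                 r$length, r$angle, r$torsion)
        }
      }
    }
  }
  atoms <- data.frame(element = rows$element, name = rows$name,
                      residue = rows$residue,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  if (is.null(bonds)) {
    b <- cbind(seq_len(n), rows$bond_ref)
    b <- b[!is.na(b[, 2]), , drop = FALSE]
    bonds <- b
  }
  glyco_structure(atoms, bonds)
}

# Place atom D given torsion ref A, angle ref B, bond ref C so that
# |CD| = r, angle(D,C,B) = theta, dihedral(D,C,B,A) = phi (IUPAC sign).
nerf_place <- function(A, B, C, r, theta_deg, phi_deg) {
  th <- theta_deg * DEG
  ph <- phi_deg * DEG
  bc <- unitv(C - B)
  ab <- B - A
  n <- cross3(ab, bc)
  if (vnorm(n) < 1e-10)
    stop("degenerate-frame error: collinear torsion reference", call. = FALSE)
  n <- unitv(n)
  m <- cross3(n, bc)
  d_local <- c(-r * cos(th), r * sin(th) * cos(ph), -r * sin(th) * sin(ph))
  C + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

#' Convert a structure to internal-coordinate rows
#'
#' Produces a topologically ordered z-matrix (each row references earlier
#' atoms) that reproduces the input geometry through
#' [zmatrix_to_cartesian()].  References prefer bonded predecessors and
#' fall back to nearest placed atoms, skipping collinear frames.
#'
#' @param structure a `glyco_structure`
#' @return data.frame of internal-coordinate rows
#' @export
cartesian_to_zmatrix <- function(structure) {
  n <- n_atoms(structure)
  xyz <- coords(structure)
  nbrs <- vector("list", n)
  for (i in seq_len(nrow(structure$bonds))) {
    a <- structure$bonds[i, 1]; b <- structure$bonds[i, 2]
    nbrs[[a]] <- c(nbrs[[a]], b)
    nbrs[[b]] <- c(nbrs[[b]], a)
  }
  pick_ref <- function(i, exclude, near_to) {
    cand <- setdiff(seq_len(i - 1L), exclude)
    if (!length(cand)) stop("no reference candidate", call. = FALSE)
    d <- sqrt(rowSums((xyz[cand, , drop = FALSE] -
                         matrix(xyz[near_to, ], length(cand), 3, byrow = TRUE))^2))
    cand[order(d)]
  }
  rows <- structure$atoms[, c("element", "name", "residue")]
  rows$bond_ref <- NA_integer_; rows$length <- NA_real_
  rows$angle_ref <- NA_integer_; rows$angle <- NA_real_
  rows$torsion_ref <- NA_integer_; rows$torsion <- NA_real_
  for (i in seq_len(n)) {
    if (i == 1) next
    prev_bonded <- nbrs[[i]][nbrs[[i]] < i]
    j <- if (length(prev_bonded)) prev_bonded[[1]] else pick_ref(i, integer(0), i)[[1]]
    rows$bond_ref[i] <- j
    rows$length[i] <- vnorm(xyz[i, ] - xyz[j, ])
    if (i == 2) next
    kc <- pick_ref(i, c(i, j), j)
    k <- NA_integer_
    for (cand in kc) {
      ang <- tryCatch(measure_angle(structure, i, j, cand), error = function(e) NA)
      if (is.finite(ang) && ang > 1 && ang < 179) { k <- cand; break }
    }
    if (is.na(k)) stop("degenerate-frame error: no angle reference", call. = FALSE)
    rows$angle_ref[i] <- k
    rows$angle[i] <- measure_angle(structure, i, j, k)
    if (i == 3) next
    lc <- pick_ref(i, c(i, j, k), k)
    l <- NA_integer_
    for (cand in lc) {
      tor <- tryCatch(dihedral_points(xyz[cand, ], xyz[k, ], xyz[j, ], xyz[i, ]),
                      error = function(e) NA)
      ang2 <- tryCatch(measure_angle(structure, cand, k, j), error = function(e) NA)
      if (is.finite(tor) && is.finite(ang2) && ang2 > 1 && ang2 < 179) {
        l <- cand; break
      }
    }
    if (is.na(l)) stop("degenerate-frame error: no torsion reference", call. = FALSE)
    rows$torsion_ref[i] <- l
    rows$torsion[i] <- dihedral_points(xyz[l, ], xyz[k, ], xyz[j, ], xyz[i, ])
  }
  rows
}

#' Apply a rigid motion to a structure
#' @param structure a `glyco_structure`
#' @param rotation 3x3 rotation matrix
#' @param translation length-3 translation vector
#' @return transformed structure
#' @export
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  xyz <- coords(structure) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  set_coords(structure, xyz)
}

random_rotation <- function() {
  # QR-based uniform-ish rotation; adequate for invariance tests
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Warn about non-bonded heavy-atom clashes
#'
#' Non-bonded heavy atoms (C, N, O) closer than `threshold` produce a
#' warning; structures are never rejected on steric grounds.
#'
#' @param structure a `glyco_structure`
#' @param threshold Angstrom, default 1.8
#' @return data.frame of clashing pairs (possibly empty), invisibly
#' @export
check_clashes <- function(structure, threshold = 1.8) {
  heavy <- which(structure$atoms$element != "H")
  xyz <- coords(structure)
  bonded <- paste(pmin(structure$bonds[, 1], structure$bonds[, 2]),
                  pmax(structure$bonds[, 1], structure$bonds[, 2]))
  out <- list()
  if (length(heavy) > 1) {
    for (ii in seq_along(heavy)[-length(heavy)]) {
      i <- heavy[ii]
      js <- heavy[(ii + 1):length(heavy)]
      d <- sqrt(rowSums((xyz[js, , drop = FALSE] -
                           matrix(xyz[i, ], length(js), 3, byrow = TRUE))^2))
      hit <- js[d < threshold]
      for (j in hit) {
        if (!(paste(min(i, j), max(i, j)) %in% bonded))
          out[[length(out) + 1]] <- data.frame(a = i, b = j,
                                               dist = vnorm(xyz[i, ] - xyz[j, ]))
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(a = integer(0), b = integer(0), dist = numeric(0))
  if (nrow(res))
    warning(sprintf("%d non-bonded heavy-atom contact(s) below %.2f Angstrom",
                    nrow(res), threshold), call. = FALSE)
  invisible(res)
}
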