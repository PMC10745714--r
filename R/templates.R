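# Built-in idealized pyranose residue templates.
#
# Residues are seeds for external quantum-chemical optimization, so the
# geometry is idealized: uniform ring bonds closing an exact tetrahedral
# chair, exocyclic bonds at standard lengths (C-C 1.53, C-O 1.43, O-H 0.96,
# N-H 1.01, C=O 1.22 Angstrom), tetrahedral centers at 109.47 degrees.

BOND_CC <- 1.53
BOND_CO <- 1.43
BOND_OH <- 0.96
BOND_CH <- 1.09
BOND_NH <- 1.01
BOND_CN <- 1.45
BOND_NC_AMIDE <- 1.35
BOND_C_O_DBL <- 1.22
ANG_TET <- 109.4712206
ANG_COH <- 107.0
RING_BOND <- 1.50
OMEGA_GG <- -60  # default hydroxymethyl rotamer (O6-C6-C5-O5)

# Exact chair with all ring angles tetrahedral: six atoms on a circle of
# radius a at 60-degree spacing, alternating heights +/- b.
chair_ring_coords <- function() {
  a <- RING_BOND * 2 * sqrt(2) / 3
  b <- a / (4 * sqrt(2))
  k <- 0:5
  ang <- k * 60 * DEG
  # C1 down, C4 up: the 4C1 chair; order C1 C2 C3 C4 C5 O5
  z <- ifelse(k %% 2 == 0, -b, b)
  cbind(a * cos(ang), a * sin(ang), z)
}

# Axial and equatorial exocyclic unit vectors at ring vertex p with ring
# neighbours n1, n2.  Axial is the direction best aligned with the ring axis.
exo_directions <- function(p, n1, n2) {
  u1 <- unitv(n1 - p)
  u2 <- unitv(n2 - p)
  w <- -unitv(u1 + u2)
  v <- unitv(cross3(u1, u2))
  delta <- (ANG_TET / 2) * DEG
  d1 <- w * cos(delta) + v * sin(delta)
  d2 <- w * cos(delta) - v * sin(delta)
  if (abs(d1[3]) >= abs(d2[3])) list(ax = d1, eq = d2) else list(ax = d2, eq = d1)
}

#' Build a built-in monosaccharide template
#'
#' Supported residues are `"alpha-D-Man"` (alpha-D-mannopyranose: axial
#' hydroxyls at C1 and C2, equatorial at C3 and C4, hydroxymethyl at C5)
#' and `"beta-D-GlcNAc"` (N-acetyl-beta-D-glucosamine: equatorial anomeric
#' hydroxyl, acetamido group at C2, equatorial hydroxyls at C3 and C4).
#' The ring is a fixed 4C1 chair; hydroxymethyl torsions default to the
#' gg staggered rotamer.
#'
#' @param name residue type, one of `"alpha-D-Man"`, `"beta-D-GlcNAc"`
#' @return a `glyco_structure` with a `sites` table of functional groups
#' @export
build_template <- function(name) {
  if (!name %in% c("alpha-D-Man", "beta-D-GlcNAc"))
    stop(sprintf("catalog error: unknown residue '%s'", name), call. = FALSE)
  ring <- chair_ring_coords()
  rn <- c("C1", "C2", "C3", "C4", "C5", "O5")
  env <- new.env()
  env$atoms <- list(); env$bonds <- list()
  add_atom <- function(element, aname, pos) {
    env$atoms[[length(env$atoms) + 1]] <- list(element = element, name = aname,
                                               pos = pos)
    length(env$atoms)
  }
  add_bond <- function(a, b) env$bonds[[length(env$bonds) + 1]] <- c(a, b)
  pos_of <- function(i) env$atoms[[i]]$pos

  idx <- integer(6)
  for (i in 1:6) idx[i] <- add_atom(ifelse(i == 6, "O", "C"), rn[i], ring[i, ])
  for (i in 1:6) add_bond(idx[i], idx[ifelse(i == 6, 1, i + 1)])

  exo <- lapply(1:6, function(i) {
    n1 <- ring[ifelse(i == 1, 6, i - 1), ]
    n2 <- ring[ifelse(i == 6, 1, i + 1), ]
    exo_directions(ring[i, ], n1, n2)
  })

  place_nerf <- function(a, b, c, r, theta, phi)
    nerf_place(pos_of(a), pos_of(b), pos_of(c), r, theta, phi)

  # hydroxyl at ring carbon ci (atom name suffix k), axial or equatorial,
  # with the hydrogen anti to the torsion reference ring atom
  sites <- list()
  add_hydroxyl <- function(k, orient, ref_ring_i) {
    ci <- idx[k]
    dir <- if (orient == "ax") exo[[k]]$ax else exo[[k]]$eq
    o <- add_atom("O", paste0("O", k), ring[k, ] + BOND_CO * dir)
    add_bond(ci, o)
    h <- add_atom("H", paste0("HO", k),
                  place_nerf(idx[ref_ring_i], ci, o, BOND_OH, ANG_COH, 180))
    add_bond(o, h)
    hs <- add_atom("H", paste0("H", k),
                   ring[k, ] + BOND_CH * (if (orient == "ax") exo[[k]]$eq else exo[[k]]$ax))
    add_bond(ci, hs)
    sites[[length(sites) + 1]] <<- list(
      label = paste0("OH", k), kind = "hydroxyl", orient = orient,
      donor_h = h, donor_heavy = o, acceptor = o,
      tq = c(idx[ref_ring_i], ci, o, h), wq = rep(NA_integer_, 4))
    o
  }

  is_man <- name == "alpha-D-Man"
  if (is_man) {
    add_hydroxyl(1, "ax", 2)   # alpha anomeric
    add_hydroxyl(2, "ax", 1)
  } else {
    add_hydroxyl(1, "eq", 2)   # beta anomeric
    # acetamido at C2
    n2 <- add_atom("N", "N2", ring[2, ] + BOND_CN * exo[[2]]$eq)
    add_bond(idx[2], n2)
    h2 <- add_atom("H", "H2", ring[2, ] + BOND_CH * exo[[2]]$ax)
    add_bond(idx[2], h2)
    c7 <- add_atom("C", "C7", place_nerf(idx[1], idx[2], n2, BOND_NC_AMIDE, 122, 180))
    add_bond(n2, c7)
    hn <- add_atom("H", "HN2", place_nerf(idx[1], idx[2], n2, BOND_NH, 118, 0))
    add_bond(n2, hn)
    o7 <- add_atom("O", "O7", place_nerf(idx[2], n2, c7, BOND_C_O_DBL, 122, 0))
    add_bond(c7, o7)
    c8 <- add_atom("C", "C8", place_nerf(idx[2], n2, c7, BOND_CC, 116, 180))
    add_bond(c7, c8)
    for (t in c(60, 180, -60)) {
      hm <- add_atom("H", paste0("H8", match(t, c(60, 180, -60))),
                     place_nerf(n2, c7, c8, BOND_CH, ANG_TET, t))
      add_bond(c8, hm)
    }
    sites[[length(sites) + 1]] <- list(
      label = "NHCO", kind = "amide", orient = "eq",
      donor_h = hn, donor_heavy = n2, acceptor = o7,
      tq = c(idx[1], idx[2], n2, hn), wq = rep(NA_integer_, 4))
  }
  add_hydroxyl(3, "eq", 2)
  add_hydroxyl(4, "eq", 3)

  # hydroxymethyl branch at C5
  c6 <- add_atom("C", "C6", ring[5, ] + BOND_CC * exo[[5]]$eq)
  add_bond(idx[5], c6)
  h5 <- add_atom("H", "H5", ring[5, ] + BOND_CH * exo[[5]]$ax)
  add_bond(idx[5], h5)
  o6 <- add_atom("O", "O6", place_nerf(idx[6], idx[5], c6, BOND_CO, ANG_TET, OMEGA_GG))
  add_bond(c6, o6)
  h61 <- add_atom("H", "H61", place_nerf(idx[6], idx[5], c6, BOND_CH, ANG_TET,
                                         wrap_angle(OMEGA_GG + 120)))
  add_bond(c6, h61)
  h62 <- add_atom("H", "H62", place_nerf(idx[6], idx[5], c6, BOND_CH, ANG_TET,
                                         wrap_angle(OMEGA_GG - 120)))
  add_bond(c6, h62)
  ho6 <- add_atom("H", "HO6", place_nerf(idx[5], c6, o6, BOND_OH, ANG_COH, 180))
  add_bond(o6, ho6)
  sites[[length(sites) + 1]] <- list(
    label = "OH6", kind = "hydroxymethyl", orient = "eq",
    donor_h = ho6, donor_heavy = o6, acceptor = o6,
    tq = c(idx[5], c6, o6, ho6), wq = c(idx[6], idx[5], c6, o6))

  # remaining ring hydrogens (H1..H4 handled with hydroxyls for Man; GlcNAc C2
  # handled with the amide); H on anomeric/substituted carbons already added.
  sites[[length(sites) + 1]] <- list(
    label = "RING_O", kind = "ring_oxygen", orient = NA,
    donor_h = NA_integer_, donor_heavy = NA_integer_, acceptor = idx[6],
    tq = rep(NA_integer_, 4), wq = rep(NA_integer_, 4))

  atoms <- data.frame(
    element = vapply(env$atoms, function(a) a$element, ""),
    name = vapply(env$atoms, function(a) a$name, ""),
    residue = "X",
    x = vapply(env$atoms, function(a) a$pos[1], 0),
    y = vapply(env$atoms, function(a) a$pos[2], 0),
    z = vapply(env$atoms, function(a) a$pos[3], 0),
    stringsAsFactors = FALSE)
  bonds <- do.call(rbind, env$bonds)
  site_df <- do.call(rbind, lapply(sites, function(s) data.frame(
    label = s$label, residue = "X", kind = s$kind,
    orient = ifelse(is.na(s$orient), NA_character_, s$orient),
    donor_h = s$donor_h, donor_heavy = s$donor_heavy, acceptor = s$acceptor,
    tq1 = s$tq[1], tq2 = s$tq[2], tq3 = s$tq[3], tq4 = s$tq[4],
    wq1 = s$wq[1], wq2 = s$wq[2], wq3 = s$wq[3], wq4 = s$wq[4],
    consumed = FALSE, stringsAsFactors = FALSE)))
  out <- glyco_structure(atoms, bonds, sites = site_df)
  attr(out, "template") <- name
  out
}

#' List functional-group site labels of a template by role
#'
#' @param template a residue template from [build_template()] (or any
#'   structure carrying a `sites` table)
#' @param role `"donor"` (sites with an H to give: hydroxyls and the amide
#'   N-H) or `"acceptor"` (any oxygen-bearing site, including the ring
#'   oxygen and the amide carbonyl)
#' @return character vector of site labels
#' @export
list_sites <- function(template, role = c("donor", "acceptor")) {
  role <- match.arg(role)
  s <- template$sites
  if (is.null(s)) stop("structure carries no site table", call. = FALSE)
  s <- s[!s$consumed, , drop = FALSE]
  if (role == "donor") s$label[!is.na(s$donor_h)] else s$label[!is.na(s$acceptor)]
}

#' Ring-closure gap of a template
#'
#' Distance between the measured C1-O5 separation and the ideal ring bond
#' length; near zero for the analytic chair.
#' @param template residue template
#' @return gap in Angstrom
#' @export
ring_closure_gap <- function(template) {
  abs(measure_distance(template, atom_index(template, template$atoms$residue[1], "C1"),
                       atom_index(template, template$atoms$residue[1], "O5")) - RING_BOND)
}

# attachment bookkeeping: position -> atom names involved in a glycosidic bond
attachment_atoms <- function(pos) {
  switch(as.character(pos),
         "1" = list(c = "C1", o = "O1", h = "HO1", site = "OH1", prev = "C2"),
         "3" = list(c = "C3", o = "O3", h = "HO3", site = "OH3", prev = "C2"),
         "4" = list(c = "C4", o = "O4", h = "HO4", site = "OH4", prev = "C3"),
         "6" = list(c = "C6", o = "O6", h = "HO6", site = "OH6", prev = "C5"),
         stop(sprintf("unsupported attachment position %s", pos), call. = FALSE))
}
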