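# Oligosaccharide assembly: glycosidic linkages, torsion presets, and the
# split-plane upper/lower partition.
#
# A linkage attaches the child's anomeric carbon (C1) to a parent oxygen
# (O3/O4/O6); condensation removes the child's anomeric hydroxyl (O + H)
# and the parent's hydroxyl hydrogen, so every linkage costs three atoms.
#
# Linkage classes are the two preset (Phi, Psi) basins:
#   cis   (syn/syn):  Phi = -80, Psi =  90
#   trans (anti/syn): Phi =  50, Psi = 120
# with Phi = ringO(child)-C1(child)-Obridge-Cx(parent) and
#      Psi = C1(child)-Obridge-Cx(parent)-C(x-1)(parent).

LINK_PRESETS <- list(cis = c(phi = -80, psi = 90),
                     trans = c(phi = 50, psi = 120))

#' Declare an oligomer topology
#'
#' @param residues data.frame with columns `tag`, `template`
#' @param linkages data.frame with columns `child`, `parent`, `parent_pos`
#'   (3, 4 or 6), `slot` (name used to address the linkage class, e.g.
#'   `"first"`); optional `bridge_label`
#' @return an `oligomer_topology`
#' @export
oligomer_topology <- function(residues, linkages) {
  stopifnot(all(c("tag", "template") %in% names(residues)))
  if (anyDuplicated(residues$tag)) stop("duplicate residue tag", call. = FALSE)
  if (is.null(linkages))
    linkages <- data.frame(child = character(0), parent = character(0),
                           parent_pos = integer(0), slot = character(0))
  if (nrow(linkages)) {
    stopifnot(all(c("child", "parent", "parent_pos", "slot") %in% names(linkages)))
    if (!all(c(linkages$child, linkages$parent) %in% residues$tag))
      stop("topology error: linkage references unknown residue", call. = FALSE)
    if (anyDuplicated(linkages$child))
      stop("topology error: residue is child of two linkages", call. = FALSE)
    key <- paste(linkages$parent, linkages$parent_pos)
    if (anyDuplicated(key))
      stop("topology error: attachment position already consumed", call. = FALSE)
    # acyclicity: child -> parent edges must reach a root
    parent_of <- stats::setNames(linkages$parent, linkages$child)
    for (tag in residues$tag) {
      seen <- character(0); cur <- tag
      while (cur %in% names(parent_of)) {
        if (cur %in% seen) stop("tree-violation error: cyclic linkage graph",
                                call. = FALSE)
        seen <- c(seen, cur); cur <- parent_of[[cur]]
      }
    }
  }
  structure(list(residues = residues, linkages = linkages),
            class = "oligomer_topology")
}

delete_atoms <- function(structure, drop) {
  keep <- setdiff(seq_len(n_atoms(structure)), drop)
  map <- rep(NA_integer_, n_atoms(structure))
  map[keep] <- seq_along(keep)
  atoms <- structure$atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  b <- structure$bonds
  if (nrow(b)) {
    ok <- !(b[, 1] %in% drop | b[, 2] %in% drop)
    b <- matrix(map[b[ok, , drop = FALSE]], ncol = 2)
  }
  s <- structure$sites
  if (!is.null(s)) {
    icols <- c("donor_h", "donor_heavy", "acceptor",
               "tq1", "tq2", "tq3", "tq4", "wq1", "wq2", "wq3", "wq4")
    for (cc in icols) s[[cc]] <- map[s[[cc]]]
  }
  out <- glyco_structure(atoms, b, sites = s)
  attr(out, "idx_map") <- map
  out
}

rotation_between <- function(v1, v2) {
  a <- unitv(v1); b <- unitv(v2)
  v <- cross3(a, b); s <- vnorm(v); c_ <- sum(a * b)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # opposite: rotate 180 about any perpendicular
    p <- if (abs(a[1]) < 0.9) unitv(cross3(a, c(1, 0, 0))) else
      unitv(cross3(a, c(0, 1, 0)))
    K <- matrix(c(0, -p[3], p[2], p[3], 0, -p[1], -p[2], p[1], 0), 3, 3,
                byrow = TRUE)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - c_) / s^2)
}

#' Assemble an oligosaccharide from a topology
#'
#' Builds every residue from its template, condenses each glycosidic
#' linkage (child C1 to parent O at `parent_pos`, removing one water
#' equivalent), and sets every linkage to its class preset torsions.
#'
#' @param topology an [oligomer_topology()]
#' @param classes named character vector mapping linkage `slot` names to
#'   `"cis"` or `"trans"`
#' @param omega default 1->6 linkage torsion O6-C6-C5-O5 of the parent,
#'   degrees (gg rotamer)
#' @return a `glyco_structure` with `sites` and a `linkages` attribute
#'   (one row per linkage with measured-torsion atom quads)
#' @export
assemble_oligomer <- function(topology, classes = NULL, omega = OMEGA_GG) {
  res <- topology$residues
  lk <- topology$linkages
  if (nrow(lk)) {
    if (is.null(classes)) stop("parameter error: linkage classes required",
                               call. = FALSE)
    miss <- setdiff(lk$slot, names(classes))
    if (length(miss))
      stop(sprintf("parameter error: no class for linkage slot(s) %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    bad <- setdiff(unlist(classes), names(LINK_PRESETS))
    if (length(bad))
      stop(sprintf("parameter error: unknown linkage class '%s'", bad[1]),
           call. = FALSE)
  }

  build_res <- function(tag) {
    tpl <- build_template(res$template[res$tag == tag])
    tpl$atoms$residue <- tag
    tpl$sites$residue <- tag
    tpl
  }

  root <- setdiff(res$tag, lk$child)
  if (length(root) != 1)
    stop("tree-violation error: topology must have exactly one root", call. = FALSE)

  combined <- build_res(root)
  placed <- root
  registry <- list()

  remap_registry <- function(map) {
    lapply(registry, function(r) {
      r$phi_quad <- map[r$phi_quad]; r$psi_quad <- map[r$psi_quad]
      if (!any(is.na(r$omega_quad))) r$omega_quad <- map[r$omega_quad]
      r
    })
  }

  pending <- lk
  while (nrow(pending)) {
    ready <- which(pending$parent %in% placed)
    if (!length(ready)) stop("tree-violation error: disconnected topology",
                             call. = FALSE)
    row <- pending[ready[1], ]
    pending <- pending[-ready[1], , drop = FALSE]

    att <- attachment_atoms(row$parent_pos)
    # parent anchor atoms
    s_parent <- combined$sites
    prow <- which(s_parent$residue == row$parent & s_parent$label == att$site &
                    !s_parent$consumed)
    if (length(prow) != 1)
      stop(sprintf("topology error: attachment %s of %s not free",
                   att$site, row$parent), call. = FALSE)
    ox <- atom_index(combined, row$parent, att$o)
    hx <- atom_index(combined, row$parent, att$h)
    cx <- atom_index(combined, row$parent, att$c)
    cprev <- atom_index(combined, row$parent, att$prev)
    xyz <- coords(combined)
    dir_oh <- unitv(xyz[hx, ] - xyz[ox, ])

    # child: drop anomeric hydroxyl, orient old C1->O1 direction onto -dir_oh
    child <- build_res(row$child)
    c1c <- atom_index(child, row$child, "C1")
    o1c <- atom_index(child, row$child, "O1")
    ho1c <- atom_index(child, row$child, "HO1")
    cxyz <- coords(child)
    v_old <- cxyz[o1c, ] - cxyz[c1c, ]
    Rm <- rotation_between(v_old, -dir_oh)
    cxyz <- sweep(cxyz, 2, cxyz[c1c, ], "-") %*% t(Rm)
    target_c1 <- xyz[ox, ] + BOND_CO * dir_oh
    cxyz <- sweep(cxyz, 2, target_c1, "+")
    child <- set_coords(child, cxyz)
    child$sites <- child$sites[child$sites$label != "OH1", , drop = FALSE]
    child <- delete_atoms(child, c(o1c, ho1c))

    # parent loses the hydroxyl hydrogen; its OHx site becomes a bridge site
    combined$sites$label[prow] <- paste0("B", row$parent_pos)
    combined$sites$kind[prow] <- "bridge_oxygen"
    combined$sites$donor_h[prow] <- NA_integer_
    combined$sites$consumed[prow] <- FALSE
    combined$sites[prow, c("tq1", "tq2", "tq3", "tq4")] <- NA_integer_
    combined <- delete_atoms(combined, hx)
    map <- attr(combined, "idx_map")
    registry <- remap_registry(map)
    ox <- map[ox]; cx <- map[cx]; cprev <- map[cprev]

    # merge
    off <- n_atoms(combined)
    atoms <- rbind(combined$atoms, child$atoms)
    bonds <- rbind(combined$bonds, child$bonds + off,
                   matrix(c(map_child <- off + atom_index(child, row$child, "C1"),
                            ox), ncol = 2))
    csites <- child$sites
    for (cc in c("donor_h", "donor_heavy", "acceptor",
                 "tq1", "tq2", "tq3", "tq4", "wq1", "wq2", "wq3", "wq4"))
      csites[[cc]] <- csites[[cc]] + off
    sites <- rbind(combined$sites, csites)
    combined <- glyco_structure(atoms, bonds, sites = sites)

    c1 <- atom_index(combined, row$child, "C1")
    o5c <- atom_index(combined, row$child, "O5")
    reg <- list(child = row$child, parent = row$parent,
                parent_pos = row$parent_pos, slot = row$slot,
                bridge_label = if ("bridge_label" %in% names(row))
                  row$bridge_label else NA_character_,
                # quads ordered so set_dihedral rotates the child side
                phi_quad = c(cx, ox, c1, o5c),
                psi_quad = c(cprev, cx, ox, c1),
                omega_quad = if (row$parent_pos == 6)
                  c(atom_index(combined, row$parent, "O5"),
                    atom_index(combined, row$parent, "C5"),
                    atom_index(combined, row$parent, "C6"), ox)
                else rep(NA_integer_, 4))
    registry[[row$slot]] <- reg
    placed <- c(placed, row$child)
  }

  attr(combined, "linkage_registry") <- registry
  attr(combined, "topology") <- topology

  # apply presets (and default omega for 1->6)
  for (slot in names(registry)) {
    r <- registry[[slot]]
    if (!any(is.na(r$omega_quad)))
      combined <- set_dihedral(combined, r$omega_quad[1], r$omega_quad[2],
                               r$omega_quad[3], r$omega_quad[4], omega)
    combined <- set_linkage_conformation(combined, slot, classes[[slot]])
  }
  combined
}

#' Set a glycosidic linkage to a class preset
#'
#' @param structure an assembled oligomer
#' @param slot linkage slot name (see [oligomer_topology()])
#' @param link_class `"cis"` or `"trans"`
#' @return structure with Phi/Psi at the preset values
#' @export
set_linkage_conformation <- function(structure, slot, link_class) {
  reg <- attr(structure, "linkage_registry")
  if (is.null(reg) || !slot %in% names(reg))
    stop(sprintf("parameter error: unknown linkage slot '%s'", slot),
         call. = FALSE)
  if (!link_class %in% names(LINK_PRESETS))
    stop(sprintf("parameter error: unknown linkage class '%s'", link_class),
         call. = FALSE)
  preset <- LINK_PRESETS[[link_class]]
  r <- reg[[slot]]
  # quads are stored child-side-last; the stored order measures the same
  # angle as the conventional ringO-C1-O-Cx order read backwards
  structure <- set_dihedral(structure, r$phi_quad[1], r$phi_quad[2],
                            r$phi_quad[3], r$phi_quad[4], preset[["phi"]])
  set_dihedral(structure, r$psi_quad[1], r$psi_quad[2],
               r$psi_quad[3], r$psi_quad[4], preset[["psi"]])
}

#' Measure the Phi/Psi torsions of a linkage
#' @param structure assembled oligomer
#' @param slot linkage slot name
#' @return named vector `c(phi=, psi=)` (and `omega` for 1->6 linkages)
#' @export
measure_linkage <- function(structure, slot) {
  reg <- attr(structure, "linkage_registry")
  if (is.null(reg) || !slot %in% names(reg))
    stop(sprintf("parameter error: unknown linkage slot '%s'", slot),
         call. = FALSE)
  r <- reg[[slot]]
  out <- c(phi = measure_dihedral(structure, r$phi_quad[1], r$phi_quad[2],
                                  r$phi_quad[3], r$phi_quad[4]),
           psi = measure_dihedral(structure, r$psi_quad[1], r$psi_quad[2],
                                  r$psi_quad[3], r$psi_quad[4]))
  if (!any(is.na(r$omega_quad)))
    out <- c(out, omega = measure_dihedral(structure, r$omega_quad[1],
                                           r$omega_quad[2], r$omega_quad[3],
                                           r$omega_quad[4]))
  out
}

#' Partition functional-group sites into upper and lower regions
#'
#' The split plane is the least-squares plane through the named ring
#' oxygens, oriented so that the majority of hydroxymethyl (C6) carbons
#' lie on the positive ("upper") side.  Every site is assigned to exactly
#' one region by the signed distance of its heavy atom.
#'
#' @param structure assembled oligomer
#' @param split_ring_oxygens atom indices of at least three ring oxygens
#' @return data.frame with columns `label`, `residue`, `region`
#' @export
partition_upper_lower <- function(structure, split_ring_oxygens) {
  if (length(split_ring_oxygens) < 3)
    stop("need at least three ring oxygens for the split plane", call. = FALSE)
  xyz <- coords(structure)
  pts <- xyz[split_ring_oxygens, , drop = FALSE]
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr, "-"))
  if (sv$d[2] < 1e-8)
    stop("degenerate-frame error: split-line oxygens are collinear", call. = FALSE)
  normal <- sv$v[, 3]
  c6 <- which(structure$atoms$name == "C6")
  side_c6 <- as.vector((xyz[c6, , drop = FALSE] -
                          matrix(ctr, length(c6), 3, byrow = TRUE)) %*% normal)
  if (sum(side_c6 > 0) < length(side_c6) / 2) normal <- -normal
  s <- structure$sites
  heavy <- ifelse(is.na(s$donor_heavy), s$acceptor, s$donor_heavy)
  d <- as.vector((xyz[heavy, , drop = FALSE] -
                    matrix(ctr, length(heavy), 3, byrow = TRUE)) %*% normal)
  # sites on the plane itself (the defining ring oxygens) count as upper;
  # the tolerance absorbs float noise from rigid motions
  data.frame(label = s$label, residue = s$residue,
             region = ifelse(d >= -1e-7, "upper", "lower"),
             stringsAsFactors = FALSE)
}
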