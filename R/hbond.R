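# Cooperative hydrogen-bond chains: arrow-notation parsing, direction
# reversal, geometric detection, conflict rules, and hydroxyl rotamer
# solving.
#
# A chain "OH6_M -> OH6' -> OH6 -> OG" is an ordered relay: each site
# donates its hydrogen to the next site's oxygen; the acceptor of one step
# is the donor of the next.  Chains may terminate on acceptor-only oxygens
# (ring oxygens, bridge oxygens, a bare anomeric oxygen).  A reversible
# chain has a clockwise and a counterclockwise variant.

#' Hydrogen-bond acceptance criteria
#'
#' The geometric criterion is a strict upper bound on the donor-oxygen to
#' acceptor-oxygen (heavy atom) distance; an optional D-H...A angle filter
#' is off by default.
#'
#' @param max_distance Angstrom, strict less-than; default 2.8
#' @param min_dha_angle optional minimum D-H...A angle in degrees
#' @return an `hbond_criteria` object
#' @export
hbond_criteria <- function(max_distance = 2.8, min_dha_angle = NULL) {
  stopifnot(is.numeric(max_distance), max_distance > 0)
  structure(list(max_distance = max_distance, min_dha_angle = min_dha_angle),
            class = "hbond_criteria")
}

# canonical label form: ASCII arrows, ASCII apostrophes, "_M" ring suffixes
normalize_chain_text <- function(text) {
  text <- gsub("→", "->", text)
  text <- gsub("[′’]", "'", text)
  text <- gsub("_([A-Za-z]+)_", "_\\1", text)  # OH6_M_ -> OH6_M
  gsub("[[:space:]]", "", text)
}

#' Build a site vocabulary
#'
#' Maps the arrow-notation labels of a catalog onto (residue, site) pairs
#' of a topology.  `role = "site"` marks a full functional group (may
#' donate); `role = "oxygen"` marks an acceptor-only oxygen reference
#' (ring oxygen, glycosidic bridge, bare anomeric oxygen).
#'
#' @param label,residue,site,role equal-length character vectors
#' @return data.frame vocabulary
#' @export
site_vocabulary <- function(label, residue, site, role) {
  stopifnot(length(label) == length(residue), length(site) == length(role),
            length(label) == length(site), all(role %in% c("site", "oxygen")))
  data.frame(label = normalize_chain_text(label), residue = residue,
             site = site, role = role, stringsAsFactors = FALSE)
}

#' Parse a hydrogen-bond chain from arrow notation
#'
#' @param text chain such as `"OH6_M->OH6'->OH6->OG"`; UTF-8 arrows and
#'   prime marks are accepted
#' @param vocab a [site_vocabulary()]; labels are resolved against it
#' @param region `"upper"` or `"lower"` (or `NA`)
#' @param reversible whether the clockwise/counterclockwise mirror is a
#'   distinct variant
#' @return an `hbond_chain`
#' @export
parse_chain_notation <- function(text, vocab, region = NA_character_,
                                 reversible = FALSE) {
  canon <- normalize_chain_text(text)
  if (!nzchar(canon)) stop("parse error: empty chain", call. = FALSE)
  tokens <- strsplit(canon, "->", fixed = TRUE)[[1]]
  if (length(tokens) < 2)
    stop("parse error: a chain needs at least two sites", call. = FALSE)
  if (any(!nzchar(tokens))) stop("parse error: empty token", call. = FALSE)
  hit <- match(tokens, vocab$label)
  if (anyNA(hit))
    stop(sprintf("vocabulary error: unknown label '%s'", tokens[which(is.na(hit))[1]]),
         call. = FALSE)
  sites <- vocab[hit, , drop = FALSE]
  rownames(sites) <- NULL
  donors <- utils::head(tokens, -1)
  if (any(sites$role[-length(tokens)] == "oxygen"))
    stop(sprintf("role error: acceptor-only site '%s' cannot donate",
                 donors[which(sites$role[-length(tokens)] == "oxygen")[1]]),
         call. = FALSE)
  if (anyDuplicated(donors))
    stop("parse error: site donates twice within one chain", call. = FALSE)
  structure(list(tokens = tokens, sites = sites, region = region,
                 reversible = reversible),
            class = "hbond_chain")
}

#' @export
print.hbond_chain <- function(x, ...) {
  cat(sprintf("<hbond_chain [%s]%s: %s>\n",
              ifelse(is.na(x$region), "?", x$region),
              ifelse(x$reversible, " reversible", ""),
              paste(x$tokens, collapse = " -> ")))
  invisible(x)
}

#' Number of donor->acceptor steps in a chain
#' @param chain an `hbond_chain`
#' @return integer
#' @export
chain_steps <- function(chain) length(chain$tokens) - 1L

#' Reverse a cooperative chain
#'
#' Terminal acceptor-only oxygens are dropped, the remaining relay is
#' reversed (donors and acceptors swap along the OH backbone).  Reversing
#' twice returns the original backbone.
#'
#' @param chain a reversible `hbond_chain`
#' @param vocab the [site_vocabulary()] used to parse it
#' @return the reversed `hbond_chain`
#' @export
reverse_chain <- function(chain, vocab) {
  if (!isTRUE(chain$reversible))
    stop("reversal error: chain is not reversible", call. = FALSE)
  tokens <- chain$tokens
  roles <- chain$sites$role
  while (length(tokens) > 1 && roles[length(tokens)] == "oxygen") {
    tokens <- tokens[-length(tokens)]
    roles <- roles[-length(roles)]
  }
  if (length(tokens) < 2)
    stop("reversal error: nothing left to reverse", call. = FALSE)
  parse_chain_notation(paste(rev(tokens), collapse = "->"), vocab,
                       region = chain$region, reversible = TRUE)
}

site_key <- function(residue, site) paste0(residue, "/", site)

# resolve chain positions to rows of a structure's site table
resolve_chain_sites <- function(chain, structure) {
  s <- structure$sites
  idx <- integer(length(chain$tokens))
  for (i in seq_along(chain$tokens)) {
    r <- which(s$residue == chain$sites$residue[i] &
                 s$label == chain$sites$site[i])
    if (length(r) != 1)
      stop(sprintf("vocabulary error: site %s/%s absent from structure",
                   chain$sites$residue[i], chain$sites$site[i]), call. = FALSE)
    idx[i] <- r
  }
  idx
}

bond_adjacency <- function(structure) {
  n <- n_atoms(structure)
  adj <- vector("list", n)
  for (i in seq_len(nrow(structure$bonds))) {
    a <- structure$bonds[i, 1]; b <- structure$bonds[i, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' Detect hydrogen bonds geometrically
#'
#' Reports donor/acceptor site pairs whose heavy-atom distance is strictly
#' below `criteria$max_distance` (2.8 Angstrom by default), excluding
#' covalently adjacent oxygens (within two bonds).  Each donor hydrogen is
#' reported at most once; the nearest acceptor wins.
#'
#' @param structure a `glyco_structure` with a `sites` table and explicit
#'   hydrogens
#' @param criteria an [hbond_criteria()]
#' @return data.frame of observations (donor, acceptor, distance, angle)
#' @export
detect_hbonds <- function(structure, criteria = hbond_criteria()) {
  s <- structure$sites
  xyz <- coords(structure)
  adj <- bond_adjacency(structure)
  donors <- which(!s$consumed & !is.na(s$donor_h))
  acceptors <- which(!is.na(s$acceptor))
  out <- list()
  for (di in donors) {
    dh <- s$donor_heavy[di]
    near2 <- unique(c(dh, unlist(adj[dh]), unlist(adj[unlist(adj[dh])])))
    best <- NULL
    for (ai in acceptors) {
      aa <- s$acceptor[ai]
      if (ai == di || aa %in% near2) next
      d <- vnorm(xyz[aa, ] - xyz[dh, ])
      if (d >= criteria$max_distance) next
      ang <- measure_angle(structure, dh, s$donor_h[di], aa)
      if (!is.null(criteria$min_dha_angle) && ang < criteria$min_dha_angle) next
      if (is.null(best) || d < best$distance)
        best <- data.frame(donor = s$label[di], donor_residue = s$residue[di],
                           acceptor = s$label[ai],
                           acceptor_residue = s$residue[ai],
                           distance = d, dha_angle = ang,
                           stringsAsFactors = FALSE)
    }
    if (!is.null(best)) out[[length(out) + 1]] <- best
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(donor = character(0), donor_residue = character(0),
               acceptor = character(0), acceptor_residue = character(0),
               distance = numeric(0), dha_angle = numeric(0))
}

#' Check a set of chains for conflicts
#'
#' Three rules: *double-donation* (one site donates in two chains),
#' *orientation-clash* (a chain needs a donor whose position was consumed
#' by a glycosidic linkage), and *mutual-pointing* (for a declared pair of
#' facing sites, both end up oriented toward each other: each side either
#' terminates a chain as a free acceptor or donates directly to the other,
#' and at least one is a free terminal acceptor).
#'
#' @param chains list of `hbond_chain`s (one direction variant)
#' @param sites site table of the assembled skeleton (for consumed flags);
#'   may be `NULL` to skip orientation-clash checks
#' @param facing_pairs list of 2-element vectors of site keys
#'   (`"residue/site"`) declared to face each other
#' @return data.frame of conflict hits (possibly empty)
#' @export
check_conflicts <- function(chains, sites = NULL, facing_pairs = list()) {
  hits <- list()
  add <- function(kind, involved)
    hits[[length(hits) + 1]] <<- data.frame(kind = kind,
                                            sites = paste(involved, collapse = " "),
                                            stringsAsFactors = FALSE)
  keys <- lapply(chains, function(ch)
    site_key(ch$sites$residue, ch$sites$site))
  donor_keys <- unlist(lapply(keys, function(k) utils::head(k, -1)))
  dup <- unique(donor_keys[duplicated(donor_keys)])
  for (d in dup) add("double-donation", d)

  if (!is.null(sites)) {
    donor_ok <- site_key(sites$residue, sites$label)[!sites$consumed &
                                                       !is.na(sites$donor_h)]
    for (d in unique(donor_keys))
      if (!d %in% donor_ok) add("orientation-clash", d)
  }

  terminal_keys <- vapply(keys, function(k) k[length(k)], "")
  all_donors <- unique(donor_keys)
  free_terminal <- setdiff(terminal_keys, all_donors)
  donates_to <- function(a, b) {
    for (k in keys)
      for (i in seq_len(length(k) - 1))
        if (k[i] == a && k[i + 1] == b) return(TRUE)
    FALSE
  }
  for (fp in facing_pairs) {
    s1 <- fp[1]; s2 <- fp[2]
    ta1 <- s1 %in% free_terminal; ta2 <- s2 %in% free_terminal
    o1 <- ta1 || donates_to(s1, s2)
    o2 <- ta2 || donates_to(s2, s1)
    if (o1 && o2 && (ta1 || ta2)) add("mutual-pointing", c(s1, s2))
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(kind = character(0), sites = character(0))
}

# positions of atom `target` as the torsion defined by quad is swept;
# thetas in degrees; returns length(thetas) x 3 matrix
sweep_torsion_positions <- function(xyz, quad, cur, target_pos, thetas) {
  origin <- xyz[quad[2], ]
  axis <- unitv(xyz[quad[3], ] - xyz[quad[2], ])
  v <- target_pos - origin
  t(vapply(thetas, function(th) origin + rodrigues(v, axis, -(th - cur)),
           numeric(3)))
}

golden_min <- function(f, lo, hi, tol = 1e-4) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c_ <- b - gr * (b - a); d_ <- a + gr * (b - a)
  fc <- f(c_); fd <- f(d_)
  while (abs(b - a) > tol) {
    if (fc < fd) { b <- d_; d_ <- c_; fd <- fc; c_ <- b - gr * (b - a); fc <- f(c_) }
    else { a <- c_; c_ <- d_; fc <- fd; d_ <- a + gr * (b - a); fd <- f(d_) }
  }
  (a + b) / 2
}

# optimize one torsion (quad) of `structure` so that the distance from the
# moving atom `probe` to the fixed point `target` is as close as possible
# to `target_dist` (0 = plain minimization); returns the chosen angle
optimize_torsion <- function(structure, quad, probe, target, target_dist = 0,
                             grid_step = 5) {
  xyz <- coords(structure)
  cur <- measure_dihedral(structure, quad[1], quad[2], quad[3], quad[4])
  # probe must move with the torsion: express via circle sweep
  grid <- seq(-180 + grid_step, 180, by = grid_step)
  pos <- sweep_torsion_positions(xyz, quad, cur, xyz[probe, ], grid)
  dd <- abs(sqrt(rowSums((pos - matrix(target, length(grid), 3,
                                       byrow = TRUE))^2)) - target_dist)
  best <- which(dd == min(dd))
  if (length(best) > 1)  # deterministic tie-break toward smaller |torsion|
    best <- best[order(abs(wrap_angle(grid[best])), grid[best])][1]
  th0 <- grid[best]
  f <- function(th) {
    p <- sweep_torsion_positions(xyz, quad, cur, xyz[probe, ], th)
    abs(vnorm(p[1, ] - target) - target_dist)
  }
  golden_min(f, th0 - grid_step, th0 + grid_step)
}

# preferred O...O separation when a hydroxymethyl torsion positions its
# oxygen for a hydrogen bond (comfortably inside the 2.8 A criterion)
OO_IDEAL <- 2.7

#' Solve hydroxyl rotamers to realize hydrogen-bond chains
#'
#' Chains are processed in order; within a chain, steps are processed from
#' the first donor.  For each step the donor hydrogen torsion (and, where
#' a hydroxymethyl group is involved, its C5-C6 torsion) is set by a
#' 5-degree grid search with golden-section refinement minimizing the
#' H...acceptor distance.  Steps whose heavy-atom separation still fails
#' the distance criterion are reported as infeasible, not fatal.
#' Afterwards, unconstrained hydroxyl torsions are set to the staggered
#' rotamer (60, -60, 180) farthest from any other hydrogen.
#'
#' @param structure assembled skeleton with a `sites` table
#' @param chains list of `hbond_chain`s (direction already chosen)
#' @param criteria an [hbond_criteria()]
#' @return list with elements `structure`, `realized` (observation table),
#'   `infeasible` (steps that cannot satisfy the criterion)
#' @export
solve_rotamers <- function(structure, chains, criteria = hbond_criteria()) {
  conf <- check_conflicts(chains, sites = structure$sites)
  if (any(conf$kind == "double-donation"))
    stop(sprintf("double-donation error: %s",
                 conf$sites[conf$kind == "double-donation"][1]), call. = FALSE)
  s <- structure$sites
  omega_set <- character(0)  # site keys whose hydroxymethyl omega is fixed
  constrained <- character(0)
  realized <- list(); infeasible <- list()

  site_row <- function(residue, site) {
    r <- which(s$residue == residue & s$label == site)
    if (length(r) != 1)
      stop(sprintf("vocabulary error: site %s/%s absent from structure",
                   residue, site), call. = FALSE)
    r
  }

  for (ch in chains) {
    rows <- vapply(seq_along(ch$tokens), function(i)
      site_row(ch$sites$residue[i], ch$sites$site[i]), 1L)
    for (k in seq_len(length(rows) - 1)) {
      di <- rows[k]; ai <- rows[k + 1]
      dkey <- site_key(s$residue[di], s$label[di])
      akey <- site_key(s$residue[ai], s$label[ai])
      if (s$consumed[di] || is.na(s$donor_h[di]))
        stop(sprintf("role error: %s cannot donate", dkey), call. = FALSE)
      constrained <- c(constrained, dkey)
      # free torsions, outermost first: acceptor omega (if not yet fixed),
      # donor omega (if not yet fixed), then the donor hydroxyl torsion;
      # a fresh donor omega gets one extra refinement pass against the
      # optimized hydroxyl.
      set_tor <- function(quad, probe, target, target_dist = 0) {
        th <- optimize_torsion(structure, quad, probe, target, target_dist)
        structure <<- set_dihedral(structure, quad[1], quad[2], quad[3],
                                   quad[4], th)
      }
      if (!is.na(s$wq1[ai]) && !(akey %in% omega_set)) {
        set_tor(c(s$wq1[ai], s$wq2[ai], s$wq3[ai], s$wq4[ai]),
                s$acceptor[ai], coords(structure)[s$donor_heavy[di], ],
                OO_IDEAL)
        omega_set <- union(omega_set, akey)
      }
      donor_wq <- c(s$wq1[di], s$wq2[di], s$wq3[di], s$wq4[di])
      donor_tq <- c(s$tq1[di], s$tq2[di], s$tq3[di], s$tq4[di])
      if (!is.na(donor_wq[1]) && !(dkey %in% omega_set)) {
        set_tor(donor_wq, s$donor_heavy[di],
                coords(structure)[s$acceptor[ai], ], OO_IDEAL)
        omega_set <- union(omega_set, dkey)
      }
      set_tor(donor_tq, s$donor_h[di], coords(structure)[s$acceptor[ai], ])
      dist <- measure_distance(structure, s$donor_heavy[di], s$acceptor[ai])
      obs <- data.frame(donor = s$label[di], donor_residue = s$residue[di],
                        acceptor = s$label[ai], acceptor_residue = s$residue[ai],
                        distance = dist,
                        dha_angle = measure_angle(structure, s$donor_heavy[di],
                                                  s$donor_h[di], s$acceptor[ai]),
                        stringsAsFactors = FALSE)
      if (dist < criteria$max_distance) realized[[length(realized) + 1]] <- obs
      else infeasible[[length(infeasible) + 1]] <- obs
    }
  }

  # unconstrained hydroxyls: staggered rotamer farthest from other hydrogens
  free <- which(!s$consumed & !is.na(s$tq1) &
                  !(site_key(s$residue, s$label) %in% constrained))
  hydrogens <- which(structure$atoms$element == "H")
  for (di in free) {
    cand <- c(60, -60, 180)
    score <- vapply(cand, function(th) {
      st <- set_dihedral(structure, s$tq1[di], s$tq2[di], s$tq3[di], s$tq4[di], th)
      xyz <- coords(st)
      others <- setdiff(hydrogens, s$donor_h[di])
      min(sqrt(rowSums((xyz[others, , drop = FALSE] -
                          matrix(xyz[s$donor_h[di], ], length(others), 3,
                                 byrow = TRUE))^2)))
    }, 0)
    th <- cand[which.max(score)]
    structure <- set_dihedral(structure, s$tq1[di], s$tq2[di], s$tq3[di],
                              s$tq4[di], th)
  }

  list(structure = structure,
       realized = if (length(realized)) do.call(rbind, realized) else
         data.frame(donor = character(0), donor_residue = character(0),
                    acceptor = character(0), acceptor_residue = character(0),
                    distance = numeric(0), dha_angle = numeric(0)),
       infeasible = if (length(infeasible)) do.call(rbind, infeasible) else
         data.frame(donor = character(0), donor_residue = character(0),
                    acceptor = character(0), acceptor_residue = character(0),
                    distance = numeric(0), dha_angle = numeric(0)))
}
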