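# Shared fixtures: small structures, vocabularies and catalogs built in
# code at test time.

# vocabulary for chains on a single free residue (tag "X")
mono_vocab <- function() {
  site_vocabulary(
    label = c("OH1", "OH2", "OH3", "OH4", "OH6", "NHCO", "O"),
    residue = rep("X", 7),
    site = c("OH1", "OH2", "OH3", "OH4", "OH6", "NHCO", "RING_O"),
    role = c(rep("site", 6), "oxygen"))
}

# vocabulary of the built-in trisaccharide catalog
tri_vocab <- function() builtin_catalog("nag2man-trisaccharide")$vocab

tri_topology <- function() {
  oligomer_topology(
    residues = data.frame(tag = c("M", "G'", "G"),
                          template = c("alpha-D-Man", "beta-D-GlcNAc",
                                       "beta-D-GlcNAc"),
                          stringsAsFactors = FALSE),
    linkages = data.frame(child = c("M", "G'"), parent = c("G'", "G"),
                          parent_pos = c(4L, 4L),
                          slot = c("first", "second"),
                          stringsAsFactors = FALSE))
}

man_glcnac_topology <- function() {
  oligomer_topology(
    residues = data.frame(tag = c("M", "G"),
                          template = c("alpha-D-Man", "beta-D-GlcNAc"),
                          stringsAsFactors = FALSE),
    linkages = data.frame(child = "M", parent = "G", parent_pos = 4L,
                          slot = "link", stringsAsFactors = FALSE))
}

# collinear O-H...O probe: donor hydroxyl pointing along +x at an
# acceptor oxygen a distance d away (heavy-atom separation)
hbond_probe <- function(d) {
  atoms <- data.frame(
    element = c("C", "O", "H", "O"),
    name = c("C1", "O1", "HO1", "O2"),
    residue = c("A", "A", "A", "B"),
    x = c(-1.2, 0, 0.96, d),
    y = c(0.6, 0, 0, 0),
    z = 0,
    stringsAsFactors = FALSE)
  sites <- data.frame(
    label = c("OH1", "ACC"), residue = c("A", "B"),
    kind = c("hydroxyl", "ring_oxygen"), orient = NA_character_,
    donor_h = c(3L, NA), donor_heavy = c(2L, NA), acceptor = c(2L, 4L),
    tq1 = NA_integer_, tq2 = NA_integer_, tq3 = NA_integer_,
    tq4 = NA_integer_, wq1 = NA_integer_, wq2 = NA_integer_,
    wq3 = NA_integer_, wq4 = NA_integer_, consumed = FALSE,
    stringsAsFactors = FALSE)
  glyco_structure(atoms, matrix(c(1L, 2L, 2L, 3L), ncol = 2, byrow = TRUE),
                  sites = sites)
}

# one-group toy catalog on a single mannose: two reversible chains that
# never conflict
toy_catalog <- function() {
  structure(list(
    name = "toy",
    molecule = "alpha-D-Man",
    topology = oligomer_topology(
      residues = data.frame(tag = "X", template = "alpha-D-Man",
                            stringsAsFactors = FALSE),
      linkages = NULL),
    vocab = mono_vocab(),
    groups = list(list(
      label = "A",
      classes = NULL,
      units = list(
        list(id = "u1", region = NA_character_, reversible = TRUE,
             fwd = "OH2->OH3", rev = NULL),
        list(id = "u2", region = NA_character_, reversible = TRUE,
             fwd = "OH4->OH6", rev = NULL)),
      facing_pairs = list(), expected_count = 4L,
      c6_rotamers = NULL, warn = NA_character_))),
    class = "motif_catalog")
}

# independent brute-force count: expand every direction assignment of a
# group and keep those with zero conflicts
brute_force_group_count <- function(group, catalog, skeleton) {
  rev_units <- Filter(function(u) u$reversible, group$units)
  ids <- vapply(rev_units, function(u) u$id, "")
  grid <- if (length(ids))
    expand.grid(rep(list(c("fwd", "rev")), length(ids)),
                stringsAsFactors = FALSE) else data.frame(row.names = 1)
  n <- 0L
  fp <- glycotree:::facing_keys(group$facing_pairs, catalog$vocab)
  for (r in seq_len(nrow(grid))) {
    dirs <- stats::setNames(rep("fwd", length(group$units)),
                            vapply(group$units, function(u) u$id, ""))
    if (length(ids)) dirs[ids] <- unlist(grid[r, ])
    chains <- unlist(mapply(function(u, d)
      glycotree:::unit_chains(u, d, catalog$vocab), group$units,
      dirs[vapply(group$units, function(u) u$id, "")], SIMPLIFY = FALSE),
      recursive = FALSE)
    conf <- check_conflicts(chains, sites = skeleton$sites,
                            facing_pairs = fp)
    if (!nrow(conf)) n <- n + 1L
  }
  n
}
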