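# Core-pentasaccharide construction by block combination.
#
# The pentasaccharide Man-a(1,3)[Man-a(1,6)]Man-b(1,4)-GlcNAc-b(1,4)-GlcNAc
# is assembled from previously analysed building blocks:
#   strategy 1 - trimannose conformers x NAG2-Man trisaccharide conformers;
#   strategy 2 - trimannose conformers x chitobiose conformers, crossed
#                with a cis/trans class for the junction linkage;
#   strategy 3 - three mannose orientations + one chitobiose block.
# Blocks are selected by an annotated relative energy threshold
# (10 kJ/mol).  Chains inherited from a block are adapted to the
# pentasaccharide topology: any step whose donor or acceptor position was
# consumed by a glycosidic bond is dropped (a hydroxyl engaged in a
# linkage has lost the hydrogen or oxygen it would need), and when the
# shared mannose's OH2 would donate in both parent blocks only the
# trisaccharide-side bond (OH2 -> OH3 of the adjacent GlcNAc) is kept --
# the OH2 -> ring-O variant duplicates a strategy-2 configuration.

#' Read a block set from a JSON file
#'
#' A block set names a source catalog and a list of entries (conformer id,
#' group, direction assignment, annotated relative energy in kJ/mol).
#'
#' @param path JSON file path
#' @return a `block_set`
#' @export
read_block_set <- function(path) {
  if (!file.exists(path)) stop(sprintf("no block-set file '%s'", path),
                               call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  entries <- lapply(raw$entries, function(e) list(
    id = e[["id"]], group = e[["group"]],
    directions = if (is.null(e[["directions"]])) character(0) else
      unlist(e[["directions"]]),
    rel_energy = as.numeric(e[["rel_energy_kjmol"]])))
  structure(list(name = raw$name, catalog = raw$catalog,
                 synthetic = isTRUE(raw$synthetic), entries = entries),
            class = "block_set")
}

BUILTIN_BLOCK_FILES <- c(
  "trimannose-lowenergy-synthetic" = "trimannose_blocks_synthetic.json",
  "nag2man-lowenergy-synthetic" = "nag2man_blocks_synthetic.json",
  "nag2-disaccharide-synthetic" = "nag2_blocks_synthetic.json")

#' Load a built-in block set
#'
#' The shipped sets carry synthetic stand-in energies (the true values
#' require external quantum-chemistry calculations); they reproduce the
#' documented selection sizes: three trimannose, two trisaccharide and two
#' chitobiose blocks inside the 10 kJ/mol window.
#'
#' @param name one of `"trimannose-lowenergy-synthetic"`,
#'   `"nag2man-lowenergy-synthetic"`, `"nag2-disaccharide-synthetic"`
#' @return a `block_set`
#' @export
builtin_block_set <- function(name) {
  if (!name %in% names(BUILTIN_BLOCK_FILES))
    stop(sprintf("unknown block set '%s'", name), call. = FALSE)
  f <- system.file("extdata", "blocks", BUILTIN_BLOCK_FILES[[name]],
                   package = "glycotree")
  if (!nzchar(f)) f <- file.path("inst", "extdata", "blocks",
                                 BUILTIN_BLOCK_FILES[[name]])
  read_block_set(f)
}

pentasaccharide_topology <- function() {
  oligomer_topology(
    residues = data.frame(
      tag = c("G", "G'", "M", "M'", "M''"),
      template = c("beta-D-GlcNAc", "beta-D-GlcNAc", "alpha-D-Man",
                   "alpha-D-Man", "alpha-D-Man"),
      stringsAsFactors = FALSE),
    linkages = data.frame(
      child = c("G'", "M", "M'", "M''"),
      parent = c("G", "G'", "M", "M"),
      parent_pos = c(4L, 4L, 3L, 6L),
      slot = c("red", "core", "man13", "man16"),
      stringsAsFactors = FALSE))
}

pentasaccharide_vocab <- function() {
  v <- list(
    c("OH2", "M", "OH2", "site"), c("OH4", "M", "OH4", "site"),
    c("OH2'", "M'", "OH2", "site"), c("OH3'", "M'", "OH3", "site"),
    c("OH4'", "M'", "OH4", "site"), c("OH6'", "M'", "OH6", "site"),
    c("OH2''", "M''", "OH2", "site"), c("OH3''", "M''", "OH3", "site"),
    c("OH4''", "M''", "OH4", "site"), c("OH6''", "M''", "OH6", "site"),
    c("OH3_G'", "G'", "OH3", "site"), c("OH6_G'", "G'", "OH6", "site"),
    c("NHCO_G'", "G'", "NHCO", "site"),
    c("OH3_G", "G", "OH3", "site"), c("OH6_G", "G", "OH6", "site"),
    c("NHCO_G", "G", "NHCO", "site"), c("OH1_G", "G", "OH1", "site"),
    c("OM", "M", "RING_O", "oxygen"), c("OM'", "M'", "RING_O", "oxygen"),
    c("OM''", "M''", "RING_O", "oxygen"),
    c("OG'", "G'", "RING_O", "oxygen"), c("OG", "G", "RING_O", "oxygen"),
    c("O1", "G", "OH1", "oxygen"),
    c("OB3", "M", "B3", "oxygen"), c("OB6", "M", "B6", "oxygen"),
    c("OB4_G'", "G'", "B4", "oxygen"), c("OB4_G", "G", "B4", "oxygen"))
  m <- do.call(rbind, v)
  site_vocabulary(m[, 1], m[, 2], m[, 3], m[, 4])
}

# chains of one block entry, as (residue, site, role) position tables
block_entry_positions <- function(set, entry, catalog) {
  gi <- which(vapply(catalog$groups, function(g) g$label, "") == entry$group)
  if (length(gi) != 1)
    stop(sprintf("block entry %s: group %s not in catalog %s", entry$id,
                 entry$group, catalog$name), call. = FALSE)
  g <- catalog$groups[[gi]]
  chains <- list()
  for (u in g$units) {
    d <- if (u$id %in% names(entry$directions)) entry$directions[[u$id]] else "fwd"
    for (ch in unit_chains(u, d, catalog$vocab))
      chains[[length(chains) + 1]] <- ch$sites[, c("residue", "site", "role")]
  }
  list(chains = chains, classes = g$classes)
}

# drop steps whose donor or acceptor position no longer exists on the
# pentasaccharide skeleton; returns a list of surviving position tables
adapt_positions <- function(pos, skeleton_sites) {
  ok_site <- function(res, site) any(skeleton_sites$residue == res &
                                       skeleton_sites$label == site)
  ok_donor <- function(res, site) {
    r <- which(skeleton_sites$residue == res & skeleton_sites$label == site)
    length(r) == 1 && !is.na(skeleton_sites$donor_h[r])
  }
  n <- nrow(pos)
  step_ok <- vapply(seq_len(n - 1), function(i)
    ok_donor(pos$residue[i], pos$site[i]) &&
      ok_site(pos$residue[i + 1], pos$site[i + 1]), TRUE)
  runs <- list()
  i <- 1
  while (i <= n - 1) {
    if (step_ok[i]) {
      j <- i
      while (j < n - 1 && step_ok[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- pos[i:(j + 1), , drop = FALSE]
      i <- j + 2
    } else i <- i + 1
  }
  runs
}

positions_to_notation <- function(pos, vocab) {
  lab <- character(nrow(pos))
  for (i in seq_len(nrow(pos))) {
    want_role <- if (i < nrow(pos)) "site" else pos$role[i]
    r <- which(vocab$residue == pos$residue[i] & vocab$site == pos$site[i] &
                 vocab$role == want_role)
    if (!length(r))  # fall back to any entry for this site
      r <- which(vocab$residue == pos$residue[i] & vocab$site == pos$site[i])
    if (!length(r))
      stop(sprintf("no pentasaccharide label for %s/%s", pos$residue[i],
                   pos$site[i]), call. = FALSE)
    lab[i] <- vocab$label[r[1]]
  }
  paste(lab, collapse = "->")
}

select_blocks <- function(set, threshold) {
  keep <- Filter(function(e) e$rel_energy <= threshold, set$entries)
  if (!length(keep))
    stop("selection error: no blocks within the energy threshold",
         call. = FALSE)
  keep
}

#' Build a core-pentasaccharide catalog by block combination
#'
#' @param strategy 1 (trisaccharide x trisaccharide), 2 (trisaccharide x
#'   disaccharide x junction class) or 3 (monosaccharide orientations +
#'   disaccharide)
#' @param man_blocks trimannose `block_set` (strategies 1-3)
#' @param nag_blocks NAG2-Man trisaccharide `block_set` (strategy 1)
#' @param di_blocks chitobiose `block_set` (strategies 2-3)
#' @param selection_threshold keep blocks with annotated relative energy
#'   at or below this many kJ/mol (default 10)
#' @return a `motif_catalog` for the pentasaccharide, enumerable by
#'   [enumerate_conformers()]
#' @export
combine_blocks <- function(strategy,
                           man_blocks = builtin_block_set("trimannose-lowenergy-synthetic"),
                           nag_blocks = builtin_block_set("nag2man-lowenergy-synthetic"),
                           di_blocks = builtin_block_set("nag2-disaccharide-synthetic"),
                           selection_threshold = 10) {
  if (!strategy %in% 1:3)
    stop("parameter error: strategy must be 1, 2 or 3", call. = FALSE)
  topo <- pentasaccharide_topology()
  vocab <- pentasaccharide_vocab()
  man_cat <- builtin_catalog(man_blocks$catalog)
  groups <- list()

  # any class assignment yields the same site inventory, so one skeleton
  # serves the adaptation checks
  skeleton <- assemble_oligomer(topo, classes = c(red = "trans",
                                                  core = "trans",
                                                  man13 = "cis",
                                                  man16 = "cis"))

  adapt_block <- function(set, entry, catalog) {
    bp <- block_entry_positions(set, entry, catalog)
    runs <- list()
    for (pos in bp$chains)
      runs <- c(runs, adapt_positions(pos, skeleton$sites))
    list(runs = runs, classes = bp$classes)
  }

  drop_oh2_duplicate <- function(man_runs, other_runs) {
    oh2_other <- any(vapply(other_runs, function(p)
      any(p$residue == "M" & p$site == "OH2" &
            seq_len(nrow(p)) < nrow(p)), TRUE))
    if (!oh2_other) return(man_runs)
    out <- list()
    for (p in man_runs) {
      don <- which(p$residue == "M" & p$site == "OH2")
      don <- don[don < nrow(p)]
      if (length(don)) {
        # split around OH2's donation; OH2 may stay as a terminal acceptor
        if (don[1] > 1) out[[length(out) + 1]] <- p[1:don[1], , drop = FALSE]
        if (don[1] + 1 < nrow(p))
          out[[length(out) + 1]] <- p[(don[1] + 1):nrow(p), , drop = FALSE]
      } else out[[length(out) + 1]] <- p
    }
    Filter(function(p) nrow(p) >= 2, out)
  }

  make_group <- function(label, classes, runs) {
    notations <- vapply(runs, positions_to_notation, "", vocab = vocab)
    list(label = label, classes = classes,
         units = list(list(id = "all", region = NA_character_,
                           reversible = FALSE, fwd = notations, rev = NULL)),
         facing_pairs = list(), expected_count = 1L,
         c6_rotamers = NULL, warn = NA_character_)
  }

  if (strategy == 1) {
    nag_cat <- builtin_catalog(nag_blocks$catalog)
    for (a in select_blocks(man_blocks, selection_threshold)) {
      for (b in select_blocks(nag_blocks, selection_threshold)) {
        am <- adapt_block(man_blocks, a, man_cat)
        bn <- adapt_block(nag_blocks, b, nag_cat)
        man_runs <- drop_oh2_duplicate(am$runs, bn$runs)
        classes <- c(man13 = unname(am$classes[["first"]]),
                     man16 = unname(am$classes[["second"]]),
                     core = unname(bn$classes[["first"]]),
                     red = unname(bn$classes[["second"]]))
        groups[[length(groups) + 1]] <-
          make_group(sprintf("S1-%sx%s", a$id, b$id), classes,
                     c(man_runs, bn$runs))
      }
    }
  } else if (strategy == 2) {
    di_cat <- builtin_catalog(di_blocks$catalog)
    for (a in select_blocks(man_blocks, selection_threshold)) {
      for (b in select_blocks(di_blocks, selection_threshold)) {
        for (jc in c("cis", "trans")) {
          am <- adapt_block(man_blocks, a, man_cat)
          bd <- adapt_block(di_blocks, b, di_cat)
          classes <- c(man13 = unname(am$classes[["first"]]),
                       man16 = unname(am$classes[["second"]]),
                       core = jc,
                       red = unname(bd$classes[["link"]]))
          groups[[length(groups) + 1]] <-
            make_group(sprintf("S2-%sx%s-%s", a$id, b$id, jc), classes,
                       c(am$runs, bd$runs))
        }
      }
    }
  } else {
    di_cat <- builtin_catalog(di_blocks$catalog)
    b <- select_blocks(di_blocks, selection_threshold)[[1]]
    bd <- adapt_block(di_blocks, b, di_cat)
    # upper mannose (1->6 arm) and lower mannose (1->3 arm) each bond
    # either to the disaccharide or to the middle mannose
    upper_opt <- list(di = "OH6''->OH6_G'", mid = "OH2''->OH2->OM")
    lower_opt <- list(di = "OH4'->OH3_G'", mid = "OH2'->OB3")
    for (u in c("di", "mid")) for (l in c("di", "mid")) {
      extra <- c(upper_opt[[u]], lower_opt[[l]])
      if (u != "mid") extra <- c(extra, "OH2->OM")
      runs <- lapply(extra, function(tx) {
        ch <- parse_chain_notation(tx, vocab)
        ch$sites[, c("residue", "site", "role")]
      })
      classes <- c(man13 = "cis", man16 = "cis", core = "trans",
                   red = unname(bd$classes[["link"]]))
      groups[[length(groups) + 1]] <-
        make_group(sprintf("S3-U%s-L%s", toupper(substr(u, 1, 1)),
                           toupper(substr(l, 1, 1))),
                   classes, c(bd$runs, runs))
    }
  }

  structure(list(name = sprintf("core-pentasaccharide-strategy%d", strategy),
                 molecule = "Man-a(1,3)[Man-a(1,6)]Man-b(1,4)-GlcNAc-b(1,4)-GlcNAc",
                 topology = topo, vocab = vocab, groups = groups),
            class = "motif_catalog")
}
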