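# Motif catalogs: the curated inventory of conformer groups.
#
# A catalog couples an oligomer topology with a site vocabulary and a list
# of groups.  Each group fixes the linkage classes (region SI of the
# building tree), a set of hydrogen-bond chain units (region SII), and the
# reversibility of each unit (region SIII: clockwise vs counterclockwise
# cooperative directions).  Groups are data, not code: catalogs ship as
# JSON under inst/extdata/catalogs and users can define their own.

#' Read a motif catalog from a JSON file
#'
#' @param path path to a catalog JSON file (see the files under
#'   `system.file("extdata", "catalogs", package = "glycotree")` for the
#'   schema)
#' @return a `motif_catalog`
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop(sprintf("catalog error: no file '%s'", path),
                               call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  req <- c("name", "topology", "vocabulary", "groups")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop(sprintf("catalog error: missing field(s) %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  residues <- do.call(rbind, lapply(raw$topology$residues, function(r)
    data.frame(tag = r$tag, template = r$template, stringsAsFactors = FALSE)))
  linkages <- if (length(raw$topology$linkages))
    do.call(rbind, lapply(raw$topology$linkages, function(l)
      data.frame(child = l$child, parent = l$parent,
                 parent_pos = as.integer(l$parent_pos), slot = l$slot,
                 stringsAsFactors = FALSE))) else NULL
  vocab <- do.call(rbind, lapply(raw$vocabulary, function(v)
    site_vocabulary(v$label, v$residue, v$site, v$role)))
  groups <- lapply(raw$groups, function(g) {
    units <- lapply(g$units, function(u) list(
      id = u[["id"]],
      region = if (is.null(u[["region"]])) NA_character_ else u[["region"]],
      reversible = isTRUE(u[["reversible"]]),
      fwd = unlist(u[["fwd"]]),
      rev = if (is.null(u[["rev"]])) NULL else unlist(u[["rev"]])))
    list(label = g$label,
         classes = unlist(g$classes),
         units = units,
         facing_pairs = if (is.null(g$facing_pairs)) list() else
           lapply(g$facing_pairs, unlist),
         expected_count = if (is.null(g$expected_count)) NA_integer_ else
           as.integer(g$expected_count),
         c6_rotamers = if (is.null(g$c6_rotamers)) NULL else
           unlist(g$c6_rotamers),
         warn = if (is.null(g$warn)) NA_character_ else g$warn)
  })
  labels <- vapply(groups, function(g) g$label, "")
  if (anyDuplicated(labels))
    stop("catalog error: duplicate group labels", call. = FALSE)
  structure(list(name = raw$name,
                 molecule = if (is.null(raw$molecule)) raw$name else raw$molecule,
                 topology = oligomer_topology(residues, linkages),
                 vocab = vocab,
                 groups = groups),
            class = "motif_catalog")
}

#' @export
print.motif_catalog <- function(x, ...) {
  cat(sprintf("<motif_catalog '%s': %s; %d residues, %d groups>\n",
              x$name, x$molecule, nrow(x$topology$residues), length(x$groups)))
  invisible(x)
}

BUILTIN_CATALOG_FILES <- c(
  "nag2man-trisaccharide" = "nag2man_trisaccharide.json",
  "trimannose" = "trimannose.json",
  "nag2-disaccharide" = "nag2_disaccharide.json")

# linkage-class suffixes accepted on the trisaccharide catalog name
TRISACCH_CLASS_SUFFIXES <- list(
  "trans-trans1" = c(first = "trans", second = "trans"),
  "trans-cis1" = c(first = "trans", second = "cis"),
  "cis-cis1" = c(first = "cis", second = "cis"),
  "cis-trans1" = c(first = "cis", second = "trans"))

catalog_file <- function(fname) {
  p <- system.file("extdata", "catalogs", fname, package = "glycotree")
  if (!nzchar(p)) p <- file.path("inst", "extdata", "catalogs", fname)
  p
}

#' Load a built-in motif catalog
#'
#' Available names: `"nag2man-trisaccharide"` (all 20 groups A-T of the
#' Man-b(1,4)-GlcNAc-b(1,4)-GlcNAc building tree), the class-filtered
#' views `"trisaccharide-trans-trans1"`, `"trisaccharide-trans-cis1"`,
#' `"trisaccharide-cis-cis1"`, `"trisaccharide-cis-trans1"`,
#' `"trimannose"` (groups A-M) and `"nag2-disaccharide"` (the
#' GlcNAc-b(1,4)-GlcNAc building block).  Core-pentasaccharide catalogs
#' are constructed at run time by [combine_blocks()].
#'
#' @param name catalog name
#' @return a `motif_catalog`
#' @export
builtin_catalog <- function(name) {
  if (name %in% names(BUILTIN_CATALOG_FILES))
    return(read_catalog(catalog_file(BUILTIN_CATALOG_FILES[[name]])))
  m <- regmatches(name, regexec("^(?:nag2man-)?trisaccharide-(.+)$", name))[[1]]
  if (length(m) == 2 && m[2] %in% names(TRISACCH_CLASS_SUFFIXES)) {
    cat_full <- builtin_catalog("nag2man-trisaccharide")
    want <- TRISACCH_CLASS_SUFFIXES[[m[2]]]
    keep <- vapply(cat_full$groups, function(g)
      all(g$classes[names(want)] == want), TRUE)
    cat_full$groups <- cat_full$groups[keep]
    cat_full$name <- name
    return(cat_full)
  }
  stop(sprintf("catalog error: unknown catalog '%s'", name), call. = FALSE)
}

# realize the chains of one unit for a given direction ("fwd"/"rev")
unit_chains <- function(unit, direction, vocab) {
  texts <- if (direction == "fwd") unit$fwd else {
    if (!is.null(unit$rev)) unit$rev else {
      if (length(unit$fwd) != 1)
        stop("catalog error: multi-chain unit needs an explicit 'rev'",
             call. = FALSE)
      ch <- parse_chain_notation(unit$fwd, vocab, region = unit$region,
                                 reversible = TRUE)
      return(list(reverse_chain(ch, vocab)))
    }
  }
  lapply(texts, parse_chain_notation, vocab = vocab, region = unit$region,
         reversible = unit$reversible)
}

# resolve facing-pair labels to residue/site keys
facing_keys <- function(pairs, vocab) {
  lapply(pairs, function(p) {
    i <- match(normalize_chain_text(p), vocab$label)
    if (anyNA(i))
      stop(sprintf("vocabulary error: unknown facing-pair label '%s'",
                   p[which(is.na(i))[1]]), call. = FALSE)
    site_key(vocab$residue[i], vocab$site[i])
  })
}

#' Validate a motif catalog
#'
#' Checks group labels, chain notation against the vocabulary, site
#' existence on the assembled skeleton, double-donation in the as-written
#' chains, and (when `expected_count` is given) agreement between the
#' derived variant count and the expectation.
#'
#' @param catalog a `motif_catalog`
#' @return data.frame of issues; zero rows means the catalog is valid
#' @export
validate_catalog <- function(catalog) {
  issues <- list()
  add <- function(group, what)
    issues[[length(issues) + 1]] <<- data.frame(group = group, issue = what,
                                                stringsAsFactors = FALSE)
  skeletons <- list()
  for (g in catalog$groups) {
    sig <- paste(c("k", g$classes), collapse = "-")
    if (is.null(skeletons[[sig]]))
      skeletons[[sig]] <- tryCatch(
        assemble_oligomer(catalog$topology, classes = g$classes),
        error = function(e) e)
    sk <- skeletons[[sig]]
    if (inherits(sk, "error")) { add(g$label, conditionMessage(sk)); next }
    chains_fwd <- tryCatch(
      unlist(lapply(g$units, unit_chains, direction = "fwd",
                    vocab = catalog$vocab), recursive = FALSE),
      error = function(e) e)
    if (inherits(chains_fwd, "error")) {
      add(g$label, conditionMessage(chains_fwd)); next
    }
    for (ch in chains_fwd) {
      ok <- tryCatch({ resolve_chain_sites(ch, sk); TRUE },
                     error = function(e) conditionMessage(e))
      if (!isTRUE(ok)) add(g$label, ok)
    }
    conf <- check_conflicts(chains_fwd, sites = sk$sites,
                            facing_pairs = list())
    for (i in seq_len(nrow(conf)))
      if (conf$kind[i] == "double-donation")
        add(g$label, sprintf("double-donation: %s", conf$sites[i]))
    if (!is.na(g$expected_count)) {
      got <- tryCatch(nrow(expand_directions(g, catalog)),
                      error = function(e) NA_integer_)
      if (!identical(got, g$expected_count))
        add(g$label, sprintf("derived count %s != expected %d",
                             got, g$expected_count))
    }
  }
  if (length(issues)) do.call(rbind, issues) else
    data.frame(group = character(0), issue = character(0))
}
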