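# The three-step tree: enumerate conformers over linkage classes (SI),
# chain motif groups (SII) and cooperative chain directions (SIII), prune
# conflicting direction variants, and build each surviving conformer.

#' Expand the direction variants of a motif group
#'
#' Takes the Cartesian product of {forward, reversed} over the group's
#' reversible units (irreversible units stay forward), in lexicographic
#' order (first unit most significant, `fwd` before `rev`), and removes
#' the variants whose realized chains hit a conflict rule.
#'
#' @param group one element of `catalog$groups`
#' @param catalog the owning `motif_catalog`
#' @param skeleton optional pre-assembled skeleton (for consumed-site
#'   checks); assembled on demand when `NULL`
#' @return data.frame with one column per unit (values `"fwd"`/`"rev"`)
#'   and attribute `pruned` holding the removed variants and their
#'   conflicts
#' @export
expand_directions <- function(group, catalog, skeleton = NULL) {
  if (is.null(skeleton))
    skeleton <- assemble_oligomer(catalog$topology, classes = group$classes)
  unit_ids <- vapply(group$units, function(u) u$id, "")
  choices <- lapply(group$units, function(u)
    if (u$reversible) c("fwd", "rev") else "fwd")
  combos <- Reduce(function(acc, ch) {
    out <- list()
    for (a in acc) for (v in ch) out[[length(out) + 1]] <- c(a, v)
    out
  }, choices, accumulate = FALSE, init = list(character(0)))
  fp <- facing_keys(group$facing_pairs, catalog$vocab)
  keep <- list(); pruned <- list()
  for (cm in combos) {
    names(cm) <- unit_ids
    chains <- unlist(mapply(function(u, d) unit_chains(u, d, catalog$vocab),
                            group$units, cm, SIMPLIFY = FALSE),
                     recursive = FALSE)
    conf <- check_conflicts(chains, sites = skeleton$sites, facing_pairs = fp)
    if (nrow(conf)) {
      pruned[[length(pruned) + 1]] <- data.frame(
        variant = paste(unit_ids, cm, sep = "=", collapse = ","),
        conflict = paste(conf$kind, conf$sites, collapse = "; "),
        stringsAsFactors = FALSE)
    } else keep[[length(keep) + 1]] <- data.frame(t(cm),
                                                  stringsAsFactors = FALSE)
  }
  out <- if (length(keep)) do.call(rbind, keep) else
    stats::setNames(data.frame(matrix(character(0), 0, length(unit_ids))),
                    unit_ids)
  attr(out, "pruned") <- if (length(pruned)) do.call(rbind, pruned) else NULL
  out
}

#' Enumerate the conformers of a motif catalog
#'
#' Walks groups in catalog order and direction variants in lexicographic
#' order; every emitted conformer has passed the conflict rules, and (when
#' `build_structures` is `TRUE`) carries its built 3D structure with
#' rotamers solved against `criteria`.
#'
#' @param catalog a `motif_catalog`
#' @param criteria an [hbond_criteria()]
#' @param build_structures build and solve the 3D structure of each
#'   conformer (set `FALSE` for a fast count-only enumeration)
#' @return an `enumeration_result`: list with `conformers` (each a
#'   `conformer_record`), `counts` (per-group data.frame), `pruned`, and
#'   `catalog_name`
#' @export
enumerate_conformers <- function(catalog, criteria = hbond_criteria(),
                                 build_structures = TRUE) {
  issues <- validate_catalog(catalog)
  if (nrow(issues))
    stop(sprintf("catalog error: %s [group %s]", issues$issue[1],
                 issues$group[1]), call. = FALSE)
  conformers <- list(); counts <- list(); pruned <- list()
  skeletons <- list()
  for (g in catalog$groups) {
    if (!is.na(g$warn))
      warning(sprintf("group %s: %s", g$label, g$warn), call. = FALSE)
    sig <- paste(c("k", g$classes), collapse = "-")
    if (is.null(skeletons[[sig]]))
      skeletons[[sig]] <- assemble_oligomer(catalog$topology,
                                            classes = g$classes)
    skeleton <- skeletons[[sig]]
    variants <- expand_directions(g, catalog, skeleton = skeleton)
    pr <- attr(variants, "pruned")
    if (!is.null(pr)) pruned[[length(pruned) + 1]] <-
      cbind(group = g$label, pr)
    n_in_group <- 0L
    for (vi in seq_len(nrow(variants))) {
      cm <- unlist(variants[vi, , drop = FALSE])
      names(cm) <- names(variants)
      n_in_group <- n_in_group + 1L
      rec <- list(id = paste0(g$label, n_in_group),
                  group = g$label,
                  catalog = catalog$name,
                  directions = cm,
                  classes = g$classes,
                  structure = NULL, realized = NULL, infeasible = NULL,
                  annotations = NULL)
      if (build_structures) {
        st <- skeleton
        if (!is.null(g$c6_rotamers)) {
          rot <- c(gg = -60, gt = 60, tg = 180)
          for (res in names(g$c6_rotamers)) {
            s <- st$sites
            r <- which(s$residue == res & s$label == "OH6" & !s$consumed)
            if (length(r) == 1)
              st <- set_dihedral(st, s$wq1[r], s$wq2[r], s$wq3[r], s$wq4[r],
                                 rot[[g$c6_rotamers[[res]]]])
          }
        }
        chains <- unlist(mapply(function(u, d)
          unit_chains(u, d, catalog$vocab), g$units, cm, SIMPLIFY = FALSE),
          recursive = FALSE)
        sol <- solve_rotamers(st, chains, criteria)
        rec$structure <- sol$structure
        rec$realized <- sol$realized
        rec$infeasible <- sol$infeasible
      }
      class(rec) <- "conformer_record"
      conformers[[length(conformers) + 1]] <- rec
    }
    counts[[length(counts) + 1]] <- data.frame(group = g$label,
                                               count = n_in_group,
                                               stringsAsFactors = FALSE)
  }
  structure(list(conformers = conformers,
                 counts = do.call(rbind, counts),
                 pruned = if (length(pruned)) do.call(rbind, pruned) else NULL,
                 catalog_name = catalog$name),
            class = "enumeration_result")
}

#' @export
print.enumeration_result <- function(x, ...) {
  cat(sprintf("<enumeration_result '%s': %d conformers in %d groups>\n",
              x$catalog_name, length(x$conformers), nrow(x$counts)))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' @export
print.conformer_record <- function(x, ...) {
  cat(sprintf("<conformer %s (group %s, %s): directions %s>\n", x$id,
              x$group, x$catalog,
              paste(names(x$directions), x$directions, sep = "=",
                    collapse = " ")))
  invisible(x)
}

#' Total conformer count of an enumeration
#' @param result an `enumeration_result`
#' @return integer
#' @export
total_conformers <- function(result) length(result$conformers)
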