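# File formats and external-engine interchange: XYZ and PDB coordinate
# files, quantum-chemistry input decks, frequency/energy tables and the
# enumeration manifest.

# 627.509474 kcal/mol per hartree times 4.184 kJ/kcal
HARTREE_KCAL <- 627.509474
KCAL_KJ <- 4.184

#' Convert hartree to kJ/mol
#' @param x energies in hartree
#' @return energies in kJ/mol
#' @export
hartree_to_kjmol <- function(x) x * HARTREE_KCAL * KCAL_KJ

#' Write a structure as an XYZ file
#'
#' Standard XYZ: atom count, comment line, then element and Cartesian
#' coordinates (Angstrom, 6 decimals) per atom.
#'
#' @param structure a `glyco_structure`
#' @param path output file
#' @param comment second-line comment
#' @return `path`, invisibly
#' @export
write_xyz <- function(structure, path, comment = "") {
  if (is.null(structure) || n_atoms(structure) == 0)
    stop("empty structure", call. = FALSE)
  xyz <- coords(structure)
  lines <- c(sprintf("%d", n_atoms(structure)), comment,
             sprintf("%-2s %12.6f %12.6f %12.6f", structure$atoms$element,
                     xyz[, 1], xyz[, 2], xyz[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read an XYZ file
#' @param path XYZ file
#' @return a `glyco_structure` (no bonds or sites)
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop(sprintf("parse error at %s:1: bad atom count", path),
                     call. = FALSE)
  if (length(lines) < n + 2)
    stop(sprintf("parse error: %s truncated", path), call. = FALSE)
  parts <- strsplit(trimws(lines[3:(n + 2)]), "[[:space:]]+")
  atoms <- data.frame(
    element = vapply(parts, `[[`, "", 1),
    name = vapply(parts, `[[`, "", 1),
    residue = "X",
    x = as.numeric(vapply(parts, `[[`, "", 2)),
    y = as.numeric(vapply(parts, `[[`, "", 3)),
    z = as.numeric(vapply(parts, `[[`, "", 4)),
    stringsAsFactors = FALSE)
  glyco_structure(atoms)
}

#' Write a structure as a PDB file (HETATM subset)
#'
#' Residue tags map to sequential residue numbers on chain A; prime marks
#' are preserved in the residue name field.  Inter-residue (glycosidic)
#' bonds are written as CONECT records.
#'
#' @param structure a `glyco_structure`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_pdb <- function(structure, path) {
  if (is.null(structure) || n_atoms(structure) == 0)
    stop("empty structure", call. = FALSE)
  xyz <- coords(structure)
  res_tags <- unique(structure$atoms$residue)
  res_seq <- match(structure$atoms$residue, res_tags)
  lines <- character(0)
  for (i in seq_len(n_atoms(structure))) {
    lines <- c(lines, sprintf(
      "HETATM%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      i, substr(structure$atoms$name[i], 1, 4), "SUG", res_seq[i],
      xyz[i, 1], xyz[i, 2], xyz[i, 3], structure$atoms$element[i]))
  }
  b <- structure$bonds
  inter <- b[structure$atoms$residue[b[, 1]] !=
               structure$atoms$residue[b[, 2]], , drop = FALSE]
  for (i in seq_len(nrow(inter)))
    lines <- c(lines, sprintf("CONECT%5d%5d", inter[i, 1], inter[i, 2]))
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read coordinates from a PDB file
#' @param path PDB file with HETATM/ATOM records
#' @return a `glyco_structure` (coordinates and elements only)
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  rec <- lines[substr(lines, 1, 6) %in% c("HETATM", "ATOM  ")]
  if (!length(rec)) stop(sprintf("parse error: no atoms in %s", path),
                         call. = FALSE)
  atoms <- data.frame(
    element = trimws(substr(rec, 77, 78)),
    name = trimws(substr(rec, 13, 16)),
    residue = trimws(substr(rec, 23, 26)),
    x = as.numeric(substr(rec, 31, 38)),
    y = as.numeric(substr(rec, 39, 46)),
    z = as.numeric(substr(rec, 47, 54)),
    stringsAsFactors = FALSE)
  glyco_structure(atoms)
}

QM_LEVELS <- c("B3LYP/6-311+G*", "B3LYP/6-31G*", "MP2/6-311++G**",
               "MP2/6-31++G**")

#' Write a quantum-chemistry input deck
#'
#' Produces a route-line text deck (Gaussian-style) with the requested
#' method/basis tag and task, charge 0 and multiplicity 1, and the
#' Cartesian block at XYZ precision.  The package only writes these
#' inputs; running them is the external engine's job.
#'
#' @param structure a `glyco_structure`
#' @param level one of `r paste(QM_LEVELS, collapse = ", ")`
#' @param task `"opt"` (geometry optimization), `"freq"` (harmonic
#'   frequencies) or `"sp"` (single point)
#' @param path output file
#' @param title deck title line
#' @return `path`, invisibly
#' @export
write_qm_input <- function(structure, level, task = c("opt", "freq", "sp"),
                           path, title = "glycotree conformer") {
  task <- match.arg(task)
  if (!level %in% QM_LEVELS)
    stop(sprintf("unknown level tag '%s'", level), call. = FALSE)
  keyword <- switch(task, opt = " Opt", freq = " Freq", sp = "")
  xyz <- coords(structure)
  lines <- c(sprintf("#P %s%s", level, keyword), "", title, "", "0 1",
             sprintf("%-2s %12.6f %12.6f %12.6f", structure$atoms$element,
                     xyz[, 1], xyz[, 2], xyz[, 3]),
             "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a frequency table
#'
#' Whitespace-delimited columns `wavenumber intensity mode_type [label]`,
#' preceded by a header comment declaring the unit
#' (`# units: cm-1`).  Parsing is total: any malformed line aborts with
#' its line number.
#'
#' @param path table file
#' @return mode data.frame (see [vibrational_modes()])
#' @export
read_frequency_table <- function(path) {
  lines <- readLines(path)
  if (!any(grepl("^#.*units:\\s*cm-?1", lines)))
    stop(sprintf("parse error: %s lacks a '# units: cm-1' header", path),
         call. = FALSE)
  body <- which(!grepl("^\\s*(#|$)", lines))
  out <- list()
  for (i in body) {
    p <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(p) < 3 || anyNA(suppressWarnings(as.numeric(p[1:2]))))
      stop(sprintf("parse error at %s:%d", path, i), call. = FALSE)
    out[[length(out) + 1]] <- data.frame(
      wavenumber = as.numeric(p[1]), intensity = as.numeric(p[2]),
      mode_type = p[3], label = if (length(p) >= 4) p[4] else NA_character_,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) stop(sprintf("parse error: %s has no modes", path),
                         call. = FALSE)
  do.call(rbind, out)
}

#' Write a frequency table
#' @param modes mode data.frame
#' @param path output file
#' @return `path`, invisibly
#' @export
write_frequency_table <- function(modes, path) {
  lines <- c("# units: cm-1",
             "# wavenumber intensity mode_type label",
             sprintf("%12.4f %12.6f %-10s %s", modes$wavenumber,
                     modes$intensity, modes$mode_type,
                     ifelse(is.na(modes$label), "-", modes$label)))
  writeLines(lines, path)
  invisible(path)
}

#' Read an energy table
#'
#' Whitespace-delimited columns `conformer_id e0k g298` (kJ/mol), with a
#' `# units: kJ/mol` header.
#'
#' @param path table file
#' @return data.frame with columns `id`, `e0k`, `g298`
#' @export
read_energy_table <- function(path) {
  lines <- readLines(path)
  if (!any(grepl("^#.*units:\\s*kJ/mol", lines)))
    stop(sprintf("parse error: %s lacks a '# units: kJ/mol' header", path),
         call. = FALSE)
  body <- which(!grepl("^\\s*(#|$)", lines))
  out <- list()
  for (i in body) {
    p <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(p) < 3 || anyNA(suppressWarnings(as.numeric(p[2:3]))))
      stop(sprintf("parse error at %s:%d", path, i), call. = FALSE)
    out[[length(out) + 1]] <- data.frame(
      id = p[1], e0k = as.numeric(p[2]), g298 = as.numeric(p[3]),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) stop(sprintf("parse error: %s empty", path), call. = FALSE)
  do.call(rbind, out)
}

#' Write an energy table
#' @param energies data.frame with `id`, `e0k`, `g298` (kJ/mol)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_energy_table <- function(energies, path) {
  lines <- c("# units: kJ/mol",
             "# conformer_id e0k g298",
             sprintf("%-12s %10.3f %10.3f", energies$id, energies$e0k,
                     energies$g298))
  writeLines(lines, path)
  invisible(path)
}

#' Attach external energies to enumeration results
#'
#' @param result an `enumeration_result`
#' @param energies data.frame from [read_energy_table()]
#' @return the result with `annotations` filled on matching conformers
#' @export
annotate_energies <- function(result, energies) {
  for (i in seq_along(result$conformers)) {
    j <- match(result$conformers[[i]]$id, energies$id)
    if (!is.na(j))
      result$conformers[[i]]$annotations <- list(e0k = energies$e0k[j],
                                                 g298 = energies$g298[j])
  }
  result
}

#' Write an enumeration manifest
#'
#' One TSV row per conformer: id, group, direction vector, structure file
#' path, and the realized hydrogen bonds.  Prime marks are preserved in
#' the table; file names use ASCII apostrophes already.
#'
#' @param result an `enumeration_result`
#' @param path output TSV
#' @param files optional character vector of per-conformer file paths
#' @return `path`, invisibly
#' @export
write_manifest <- function(result, path, files = NA_character_) {
  rows <- lapply(seq_along(result$conformers), function(i) {
    cf <- result$conformers[[i]]
    data.frame(
      id = cf$id, group = cf$group,
      directions = paste(names(cf$directions), cf$directions, sep = "=",
                         collapse = ","),
      file = if (length(files) >= i) files[i] else NA_character_,
      hbonds = if (is.null(cf$realized) || !nrow(cf$realized)) "" else
        paste(sprintf("%s(%s)->%s(%s)", cf$realized$donor,
                      cf$realized$donor_residue, cf$realized$acceptor,
                      cf$realized$acceptor_residue), collapse = ";"),
      stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an enumeration manifest
#' @param path manifest TSV
#' @return data.frame
#' @export
read_manifest <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, quote = "")
}
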