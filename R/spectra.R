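# Post-processing of externally computed harmonic frequencies and
# energies: mode-type frequency scaling, band broadening, Boltzmann
# population weighting and conformer ranking.
#
# The package never computes quantum-chemical quantities itself; it
# prepares inputs for and digests tables from an external engine.

R_GAS_KJ <- 0.0083144626181532  # kJ/(mol K)

#' Harmonic frequency scale factors
#'
#' Empirical multipliers bringing computed harmonic stretch wavenumbers
#' into accord with experiment.  Defaults: 0.9734 for O-H stretch modes,
#' 0.9600 for N-H stretch modes (B3LYP/6-311+G*), and a global 0.9603 for
#' the cheaper B3LYP/6-31G* level used on large systems; non-stretch
#' (`other`) modes default to 1.
#'
#' @param oh_stretch,nh_stretch,other per-type factors
#' @param global_b3lyp_631g the single-factor alternative
#' @return a `scale_factor_set`
#' @export
scale_factor_set <- function(oh_stretch = 0.9734, nh_stretch = 0.9600,
                             other = 1.0, global_b3lyp_631g = 0.9603) {
  f <- c(`OH-stretch` = oh_stretch, `NH-stretch` = nh_stretch,
         other = other, global = global_b3lyp_631g)
  if (any(f <= 0.8 | f > 1))
    stop("scale factors must lie in (0.8, 1]", call. = FALSE)
  structure(as.list(f), class = "scale_factor_set")
}

#' Create a table of vibrational modes
#' @param wavenumber cm^-1, > 0
#' @param intensity arbitrary units, >= 0
#' @param mode_type `"OH-stretch"`, `"NH-stretch"` or `"other"`
#' @param label optional site-based tags (e.g. a C3 hydroxyl stretch)
#' @return data.frame of modes
#' @export
vibrational_modes <- function(wavenumber, intensity,
                              mode_type = "OH-stretch",
                              label = NA_character_) {
  stopifnot(all(wavenumber > 0), all(intensity >= 0))
  data.frame(wavenumber = wavenumber, intensity = intensity,
             mode_type = rep_len(mode_type, length(wavenumber)),
             label = rep_len(label, length(wavenumber)),
             stringsAsFactors = FALSE)
}

#' Scale harmonic frequencies by mode type
#'
#' @param modes data.frame from [vibrational_modes()] or
#'   [read_frequency_table()]
#' @param factors a [scale_factor_set()]
#' @param use_global apply the single global factor (B3LYP/6-31G* usage)
#'   to every mode instead of per-type factors
#' @return modes with scaled wavenumbers; intensities unchanged
#' @export
scale_frequencies <- function(modes, factors = scale_factor_set(),
                              use_global = FALSE) {
  if (use_global) {
    modes$wavenumber <- modes$wavenumber * factors$global
    return(modes)
  }
  known <- c("OH-stretch", "NH-stretch", "other")
  bad <- setdiff(unique(modes$mode_type), known)
  if (length(bad))
    stop(sprintf("mapping error: no scale factor for mode type '%s'", bad[1]),
         call. = FALSE)
  fac <- c(factors$`OH-stretch`, factors$`NH-stretch`, factors$other)
  modes$wavenumber <- modes$wavenumber *
    fac[match(modes$mode_type, known)]
  modes
}

#' Broaden a stick spectrum into a band envelope
#'
#' Each mode contributes a normalized Gaussian or Lorentzian of full width
#' at half maximum `fwhm` scaled by its intensity, so the integrated curve
#' area equals the summed stick intensities.
#'
#' @param modes mode table
#' @param shape `"gaussian"` or `"lorentzian"`
#' @param fwhm full width at half maximum, cm^-1 (default 15)
#' @param grid evaluation grid in cm^-1; defaults to the mode range padded
#'   by 5 fwhm at 0.5 cm^-1 spacing
#' @return data.frame with columns `wavenumber`, `intensity`
#' @export
broaden_spectrum <- function(modes, shape = c("gaussian", "lorentzian"),
                             fwhm = 15, grid = NULL) {
  shape <- match.arg(shape)
  if (is.null(modes) || nrow(modes) == 0)
    stop("empty-spectrum error: no modes to broaden", call. = FALSE)
  stopifnot(fwhm > 0)
  if (is.null(grid))
    grid <- seq(min(modes$wavenumber) - 5 * fwhm,
                max(modes$wavenumber) + 5 * fwhm, by = 0.5)
  y <- numeric(length(grid))
  if (shape == "gaussian") {
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    for (i in seq_len(nrow(modes)))
      y <- y + modes$intensity[i] *
        stats::dnorm(grid, modes$wavenumber[i], sigma)
  } else {
    gam <- fwhm / 2
    for (i in seq_len(nrow(modes)))
      y <- y + modes$intensity[i] * (gam / pi) /
        ((grid - modes$wavenumber[i])^2 + gam^2)
  }
  data.frame(wavenumber = grid, intensity = y)
}

#' Thermochemistry configuration
#' @param temperature Kelvin, default 298.15
#' @param gas_constant kJ/(mol K)
#' @return a `thermo_config`
#' @export
thermo_config <- function(temperature = 298.15, gas_constant = R_GAS_KJ) {
  stopifnot(temperature > 0, gas_constant > 0)
  structure(list(temperature = temperature, gas_constant = gas_constant),
            class = "thermo_config")
}

#' Boltzmann population weights
#'
#' Weights proportional to exp(-dG / RT) relative to the minimum energy;
#' they sum to one and decrease with increasing energy.
#'
#' @param free_energies kJ/mol (any common offset cancels)
#' @param config a [thermo_config()]
#' @return numeric weights summing to 1
#' @export
boltzmann_weights <- function(free_energies, config = thermo_config()) {
  if (!length(free_energies)) stop("no energies given", call. = FALSE)
  if (any(is.na(free_energies)))
    stop("non-finite free energy", call. = FALSE)
  x <- free_energies - min(free_energies[is.finite(free_energies)])
  w <- exp(-x / (config$gas_constant * config$temperature))
  w[is.nan(w)] <- 0
  w / sum(w)
}

#' Rank conformer records by an energy annotation
#'
#' Stable ascending sort by the requested annotation; ties keep input
#' order.  The result carries a `rank_changes` attribute listing records
#' whose rank under the other key differs (the 0 K ordering versus the
#' 298.15 K Gibbs ordering can disagree).
#'
#' @param records list of `conformer_record`s with `annotations` holding
#'   `e0k` and/or `g298` (kJ/mol)
#' @param key `"0K"` or `"gibbs298"`
#' @return the reordered list, with attribute `rank_changes`
#' @export
rank_conformers <- function(records, key = c("0K", "gibbs298")) {
  key <- match.arg(key)
  field <- if (key == "0K") "e0k" else "g298"
  other <- if (key == "0K") "g298" else "e0k"
  get <- function(f) vapply(records, function(r) {
    v <- r$annotations[[f]]
    if (is.null(v)) NA_real_ else v
  }, 0)
  e <- get(field)
  if (anyNA(e))
    stop(sprintf("annotation error: missing '%s' on some records", field),
         call. = FALSE)
  ord <- order(e)  # stable in R
  out <- records[ord]
  eo <- get(other)
  changes <- NULL
  if (!anyNA(eo)) {
    ord2 <- order(eo)
    r1 <- match(seq_along(records), ord)
    r2 <- match(seq_along(records), ord2)
    moved <- which(r1 != r2)
    if (length(moved))
      changes <- data.frame(
        id = vapply(records[moved], function(r) r$id, ""),
        rank_primary = r1[moved], rank_other = r2[moved],
        stringsAsFactors = FALSE)
  }
  attr(out, "rank_changes") <- changes
  out
}
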