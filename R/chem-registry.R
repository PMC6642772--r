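#' Physical constants used throughout the package
#'
#' Returns the ideal gas constant and the Faraday constant used by the
#' thermodynamic and electrochemical calculations. The gas constant is fixed
#' at 8.314e-3 kJ/(mol K) (8.314 J/(mol K)); the Faraday constant defaults to
#' the CODATA value 96485 C/mol but may be set to the rounded 96500 C/mol that
#' older electrochemistry tables use. At two-decimal precision in volts the
#' two choices are indistinguishable.
#'
#' @param faraday Faraday constant in C/mol.
#' @return A list with elements `R_kJ` (kJ/(mol K)), `R_J` (J/(mol K)) and
#'   `faraday` (C/mol).
#' @examples
#' physical_constants()
#' physical_constants(faraday = 96500)
#' @export
physical_constants <- function(faraday = 96485) {
  stopifnot(is.numeric(faraday), length(faraday) == 1, faraday > 0)
  list(R_kJ = 8.314e-3, R_J = 8.314, faraday = faraday)
}

#' Chemical species registry
#'
#' The species handled by the package, with the element basis on which
#' mass concentrations are reported. Nitrogen species are measured as mg N/L,
#' sulfur species as mg S/L, and dissolved oxygen as mg O2/L (whole molecule),
#' matching the usual reporting convention of wastewater data. The
#' `basis_mass` column is the mass of one mole of the basis (mg/mol), so a
#' molar concentration is `mg_per_L / basis_mass`.
#'
#' Solids, gases and the solvent carry unit activity in reaction quotients;
#' they are included here so stoichiometries can be balance-checked.
#'
#' @param extra Optional data.frame of additional species with the same
#'   columns (`identifier`, `basis`, `basis_mass`, `phase`), appended to the
#'   built-in registry.
#' @return A data.frame with columns `identifier`, `basis`, `basis_mass`
#'   (mg per mol of basis; NA for solids and solvent) and `phase`.
#' @examples
#' species_registry()
#' @export
species_registry <- function(extra = NULL) {
  reg <- data.frame(
    identifier = c("NH4+", "NO2-", "NO3-", "N2", "N2O",
                   "O2", "HS-", "S2-", "SO4-2", "S0", "H+", "H2O"),
    basis      = c("N", "N", "N", "N", "N",
                   "O2", "S", "S", "S", "S", "H", "none"),
    basis_mass = c(14000, 14000, 14000, 14000, 14000,
                   32000, 32000, 32000, 32000, NA, 1000, NA),
    phase      = c("aqueous", "aqueous", "aqueous", "gas", "gas",
                   "aqueous", "aqueous", "aqueous", "aqueous", "solid",
                   "aqueous", "solvent"),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) {
    need <- c("identifier", "basis", "basis_mass", "phase")
    if (!all(need %in% names(extra)))
      stop("`extra` must have columns: ", paste(need, collapse = ", "))
    reg <- rbind(reg, extra[, need])
  }
  reg
}

#' Convert an element-basis mass concentration to molar
#'
#' Concentrations in reactor data sets are reported on an element basis
#' (mg N/L for nitrogen species, mg S/L for sulfur species) or as mg O2/L for
#' dissolved oxygen. This converts such a value to mol/L by dividing by the
#' molar mass of the basis.
#'
#' @param species Species identifier (see [species_registry()]).
#' @param mg_per_l Concentration in mg (of basis element, or O2) per liter.
#'   Vectorized.
#' @param registry Species registry data.frame.
#' @return Molar concentration (mol/L).
#' @examples
#' to_molar("NO3-", 14)       # 0.001 M
#' to_molar("O2", 32)         # 0.001 M
#' to_molar("SO4-2", 205)     # 205/32000 M
#' @export
to_molar <- function(species, mg_per_l, registry = species_registry()) {
  row <- match(species, registry$identifier)
  if (is.na(row))
    stop("species not registered: ", species)
  if (any(mg_per_l < 0, na.rm = TRUE))
    stop("negative concentration for ", species)
  bm <- registry$basis_mass[row]
  if (is.na(bm))
    stop("species ", species, " (", registry$phase[row],
         ") has fixed unit activity and no molar concentration")
  mg_per_l / bm
}

#' Convert a molar concentration back to the element-basis mass scale
#'
#' Inverse of [to_molar()].
#'
#' @inheritParams to_molar
#' @param molar Concentration in mol/L.
#' @return Concentration in mg (basis)/L.
#' @export
from_molar <- function(species, molar, registry = species_registry()) {
  row <- match(species, registry$identifier)
  if (is.na(row))
    stop("species not registered: ", species)
  bm <- registry$basis_mass[row]
  if (is.na(bm))
    stop("species ", species, " has no molar concentration scale")
  molar * bm
}

#' Proton activity from pH
#'
#' @param ph pH value(s) in \[0, 14\].
#' @return Molar activity of H+, `10^(-pH)`.
#' @examples
#' proton_activity(7)    # 1e-7
#' proton_activity(9.3)
#' @export
proton_activity <- function(ph) {
  if (any(!is.finite(ph)) || any(ph < 0) || any(ph > 14))
    stop("pH must lie in [0, 14]")
  10^(-ph)
}

#' Bulk-liquid state of a reactor stage
#'
#' Bundles the pH, absolute temperature and the measured concentrations of a
#' reactor's bulk liquid into the state object consumed by the thermodynamic
#' functions. Concentrations are named by species identifier and given on the
#' element basis (mg N/L, mg S/L) or mg O2/L for dissolved oxygen.
#'
#' @param ph pH of the bulk liquid, in \[0, 14\].
#' @param temperature_k Absolute temperature in Kelvin.
#' @param conc Named numeric vector of concentrations (mg basis/L).
#' @return An object of class `stage_state`.
#' @examples
#' stage_state(7.5, 296.15, c("NH4+" = 9, "NO2-" = 3, "O2" = 0.5))
#' @export
stage_state <- function(ph, temperature_k, conc = numeric()) {
  if (!is.finite(ph) || ph < 0 || ph > 14)
    stop("pH must lie in [0, 14]")
  if (!is.finite(temperature_k) || temperature_k <= 0)
    stop("temperature must be positive (Kelvin)")
  conc <- unlist(conc)
  if (length(conc) && (is.null(names(conc)) || any(!nzchar(names(conc)))))
    stop("`conc` must be a named vector of species concentrations")
  if (any(conc < 0, na.rm = TRUE))
    stop("concentrations must be nonnegative")
  structure(list(ph = ph, temperature_k = temperature_k, conc = conc),
            class = "stage_state")
}

#' @export
print.stage_state <- function(x, ...) {
  cat(sprintf("Bulk-liquid state: pH %.2f, T %.2f K\n", x$ph, x$temperature_k))
  if (length(x$conc)) {
    cat("Concentrations (mg basis/L):\n")
    print(x$conc)
  }
  invisible(x)
}
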