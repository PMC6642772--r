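#' Load the candidate redox reactions
#'
#' Reads the shipped reaction definitions: two ammonia-oxidation reactions
#' (to nitrite and to nitrous oxide) and six sulfur-driven denitrification
#' reactions covering sulphide or elemental sulfur as electron donor and
#' nitrite, nitrogen gas or sulfate as products. Each reaction carries its
#' stoichiometry, the number of electrons transferred, the standard Gibbs
#' free energy (kJ per reaction as written) and the exponents of its
#' reaction quotient.
#'
#' @param process Optional filter: `"nitrification"` or `"denitrification"`.
#' @param path Path to a reaction definition JSON file; defaults to the
#'   definitions shipped with the package.
#' @return A named list of `redox_reaction` objects.
#' @examples
#' rxns <- load_reactions()
#' names(rxns)
#' rxns[["ii"]]$dg0_kj
#' @export
load_reactions <- function(process = NULL, path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reactions.json", package = "oxcap",
                        mustWork = TRUE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)$reactions
  rxns <- lapply(raw, function(r) {
    structure(list(
      id = r$id, process = r$process, label = r$label,
      stoichiometry = unlist(r$stoichiometry),
      electrons = r$electrons, dg0_kj = r$dg0_kj,
      quotient = unlist(r$quotient)
    ), class = "redox_reaction")
  })
  names(rxns) <- vapply(rxns, `[[`, "", "id")
  if (!is.null(process)) {
    process <- match.arg(process, c("nitrification", "denitrification"))
    rxns <- rxns[vapply(rxns, `[[`, "", "process") == process]
  }
  rxns
}

#' @export
print.redox_reaction <- function(x, ...) {
  cat(sprintf("(%s) %s  [%d e-, dG0 = %.1f kJ]\n",
              x$id, x$label, x$electrons, x$dg0_kj))
  invisible(x)
}

#' Check the elemental and charge balance of a reaction
#'
#' Verifies that nitrogen, sulfur, oxygen, hydrogen and charge balance over
#' the reaction's stoichiometry. Used by the test suite to guard the shipped
#' reaction table against transcription errors.
#'
#' @param reaction A `redox_reaction`.
#' @return Named numeric vector of imbalances (all zero for a valid
#'   reaction): N, S, O, H, charge.
#' @export
reaction_balance <- function(reaction) {
  comp <- list(
    "NH4+" = c(N = 1, H = 4, charge = 1),
    "NO2-" = c(N = 1, O = 2, charge = -1),
    "NO3-" = c(N = 1, O = 3, charge = -1),
    "N2"   = c(N = 2),
    "N2O"  = c(N = 2, O = 1),
    "O2"   = c(O = 2),
    "HS-"  = c(S = 1, H = 1, charge = -1),
    "SO4-2" = c(S = 1, O = 4, charge = -2),
    "S0"   = c(S = 1),
    "H+"   = c(H = 1, charge = 1),
    "H2O"  = c(H = 2, O = 1)
  )
  bal <- c(N = 0, S = 0, O = 0, H = 0, charge = 0)
  for (sp in names(reaction$stoichiometry)) {
    if (is.null(comp[[sp]]))
      stop("no composition known for species ", sp)
    v <- comp[[sp]]
    bal[names(v)] <- bal[names(v)] + reaction$stoichiometry[[sp]] * v
  }
  bal
}

## Resolve the activity of one quotient species. Unmeasured gases default to
## unit activity; measured aqueous concentrations of exactly zero are floored
## at `conc_floor` so log Q stays finite (with a warning).
.species_activity <- function(species, state, activity_overrides, registry,
                              conc_floor) {
  if (!is.null(activity_overrides) && species %in% names(activity_overrides)) {
    a <- activity_overrides[[species]]
    if (!is.finite(a) || a <= 0)
      stop("activity override for ", species, " must be positive and finite")
    return(a)
  }
  if (species == "H+")
    return(proton_activity(state$ph))
  row <- match(species, registry$identifier)
  if (is.na(row))
    stop("species not registered: ", species)
  phase <- registry$phase[row]
  if (phase %in% c("solid", "solvent"))
    return(1)
  if (phase == "gas")
    return(1)  # unmeasured dissolved gas: unit activity unless overridden
  if (!(species %in% names(state$conc)))
    stop("no concentration for aqueous species ", species,
         " in state and no activity override given")
  m <- to_molar(species, state$conc[[species]], registry)
  if (m < conc_floor) {
    warning("concentration of ", species, " floored at ", conc_floor,
            " M inside the reaction quotient", call. = FALSE)
    m <- conc_floor
  }
  m
}

#' Reaction quotient of a redox reaction in a given bulk-liquid state
#'
#' Evaluates Q as the product of species activities raised to their signed
#' stoichiometric exponents. Aqueous activities come from the element-basis
#' concentrations in `state` (ideal solution, activity coefficient 1), the
#' proton activity from the state's pH. Solids and water are excluded (unit
#' activity); dissolved gases with no measured concentration (N2, N2O) enter
#' at unit activity unless an explicit override is supplied.
#'
#' @param reaction A `redox_reaction` from [load_reactions()].
#' @param state A [stage_state()].
#' @param activity_overrides Optional named list of molar activities that
#'   take precedence over the state's concentrations (e.g. a measured
#'   dissolved N2O activity).
#' @param registry Species registry.
#' @param conc_floor Floor (mol/L) applied to measured concentrations of
#'   exactly or nearly zero before taking logarithms, with a warning;
#'   prevents silently infinite quotients.
#' @return Dimensionless Q.
#' @examples
#' rxn <- load_reactions()[["i"]]
#' st <- stage_state(7, 298.15, c("NO2-" = 14, "NH4+" = 14, "O2" = 32))
#' reaction_quotient(rxn, st)  # (1e-3 * 1e-14) / (1e-3 * 1e-3^1.5)
#' @export
reaction_quotient <- function(reaction, state, activity_overrides = NULL,
                              registry = species_registry(),
                              conc_floor = 1e-12) {
  exp(.log_quotient(reaction, state, activity_overrides, registry, conc_floor))
}

.log_quotient <- function(reaction, state, activity_overrides, registry,
                          conc_floor) {
  q <- reaction$quotient
  sum(vapply(names(q), function(sp) {
    q[[sp]] * log(.species_activity(sp, state, activity_overrides,
                                    registry, conc_floor))
  }, numeric(1)))
}

#' Gibbs free energy of a reaction under bulk-liquid conditions
#'
#' Computes `dG = dG0 + R T ln Q` in kJ per reaction as written, with the
#' reaction quotient evaluated from the state's concentrations.
#'
#' @inheritParams reaction_quotient
#' @param constants Physical constants, see [physical_constants()].
#' @return Gibbs free energy in kJ (per reaction as written).
#' @examples
#' rxn <- load_reactions()[["i"]]
#' st <- stage_state(7, 298.15, c("NO2-" = 14, "NH4+" = 14, "O2" = 32))
#' delta_g(rxn, st)
#' @export
delta_g <- function(reaction, state, activity_overrides = NULL,
                    registry = species_registry(), conc_floor = 1e-12,
                    constants = physical_constants()) {
  lnq <- .log_quotient(reaction, state, activity_overrides, registry,
                       conc_floor)
  reaction$dg0_kj + constants$R_kJ * state$temperature_k * lnq
}

#' Gibbs free energy per mole of electrons transferred
#'
#' The package's metric for comparing energetic favorability across reactions
#' with different electron counts: [delta_g()] divided by the number of
#' electrons the reaction transfers.
#'
#' @inheritParams delta_g
#' @return kJ per mol e-.
#' @examples
#' rxns <- load_reactions()
#' st <- stage_state(7, 298.15)
#' # at unit activities: dG0 / n
#' delta_g_per_electron(rxns[["i"]], st, activity_overrides =
#'   list("NO2-" = 1, "NH4+" = 1, "O2" = 1))
#' @export
delta_g_per_electron <- function(reaction, state, activity_overrides = NULL,
                                 registry = species_registry(),
                                 conc_floor = 1e-12,
                                 constants = physical_constants()) {
  delta_g(reaction, state, activity_overrides, registry, conc_floor,
          constants) / reaction$electrons
}

#' Rank candidate reactions by energetic favorability
#'
#' Orders reactions by Gibbs free energy per mole of electrons, most negative
#' (most favorable) first, under the given bulk-liquid state. Microorganisms
#' are expected to preferentially use the most energetically favorable
#' reactions, so the top of this ranking is the predicted dominant pathway.
#' Ties are broken by the reactions' order in the input list (stable sort).
#'
#' @param reactions A list of `redox_reaction` objects.
#' @inheritParams delta_g
#' @return A data.frame with columns `id`, `label`, `electrons`,
#'   `dg_kj` and `dg_per_e_kj`, sorted by `dg_per_e_kj` ascending.
#' @export
rank_reactions <- function(reactions, state, activity_overrides = NULL,
                           registry = species_registry(), conc_floor = 1e-12,
                           constants = physical_constants()) {
  if (!length(reactions)) stop("at least one reaction is required")
  dg <- vapply(reactions, delta_g, numeric(1), state = state,
               activity_overrides = activity_overrides, registry = registry,
               conc_floor = conc_floor, constants = constants)
  n <- vapply(reactions, `[[`, numeric(1), "electrons")
  out <- data.frame(
    id = vapply(reactions, `[[`, "", "id"),
    label = vapply(reactions, `[[`, "", "label"),
    electrons = n, dg_kj = dg, dg_per_e_kj = dg / n,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(out$dg_per_e_kj, seq_len(nrow(out))), , drop = FALSE]
}
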