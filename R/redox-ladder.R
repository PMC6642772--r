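#' Load the half-reaction definitions
#'
#' Reads the shipped reduction half-reactions for ammonia oxidation (O2/H2O,
#' N2O/NH4+, NO2-/NH4+) and sulfur-driven autotrophic denitrification
#' (NO3-/N2, NO2-/N2, SO4-2/HS-, S0/HS-). Each row carries the standard
#' potential `e0_v` at pH 0 and unit oxidized/reduced activity ratio, and the
#' protons-per-electron coefficient `m` (as a rational `m_num/m_den`) that
#' sets the Nernstian pH slope.
#'
#' @param process Optional filter: `"nitrification"` or `"denitrification"`.
#' @param path Path to a half-reaction CSV; defaults to the shipped table.
#' @return A data.frame with columns `id`, `process`, `oxidized`, `reduced`,
#'   `label`, `e0_v`, `m_num`, `m_den` and computed `m`.
#' @examples
#' load_half_reactions("nitrification")
#' @export
load_half_reactions <- function(process = NULL, path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "half_reactions.csv", package = "oxcap",
                        mustWork = TRUE)
  hr <- utils::read.csv(path, stringsAsFactors = FALSE)
  hr$m <- hr$m_num / hr$m_den
  if (!is.null(process)) {
    process <- match.arg(process, c("nitrification", "denitrification"))
    hr <- hr[hr$process == process, , drop = FALSE]
    rownames(hr) <- NULL
  }
  hr
}

#' pH-corrected half-reaction potential
#'
#' The reduction potential of a couple at the given pH and temperature,
#' holding the oxidized/reduced activity ratio at 1:
#' `E_H = E0 - (2.303 R T / F) * m * pH`, with R in J/(mol K). The factor
#' 2.303 is the conventional decadic-logarithm conversion used in
#' electrochemical tables (ln 10 to four significant figures).
#'
#' @param half_reaction One row of [load_half_reactions()] (or a data.frame
#'   of several rows; vectorized over rows).
#' @param ph pH in \[0, 14\].
#' @param temperature_k Absolute temperature (K).
#' @param constants Physical constants, see [physical_constants()].
#' @param decadic_slope_v Optional fixed Nernst slope in V per pH unit,
#'   replacing `2.303 R T / F`. Electrochemistry handbooks conventionally
#'   tabulate the two-significant-figure value 0.059 V for temperatures near
#'   25 C; passing it reproduces tables compiled under that convention.
#' @return Potential(s) in volts vs the standard hydrogen electrode.
#' @examples
#' hr <- load_half_reactions("nitrification")
#' half_potential(hr, ph = 7.5, temperature_k = 296.15)
#' @export
half_potential <- function(half_reaction, ph, temperature_k,
                           constants = physical_constants(),
                           decadic_slope_v = NULL) {
  if (any(!is.finite(ph)) || any(ph < 0) || any(ph > 14))
    stop("pH must lie in [0, 14]")
  if (any(!is.finite(temperature_k)) || any(temperature_k <= 0))
    stop("temperature must be positive (Kelvin)")
  slope <- if (is.null(decadic_slope_v)) {
    2.303 * constants$R_J * temperature_k / constants$faraday
  } else {
    decadic_slope_v
  }
  half_reaction$e0_v - slope * half_reaction$m * ph
}

#' Assemble a redox ladder
#'
#' Computes the pH-corrected potential of every couple and orders them from
#' the strongest oxidant (highest E_H) down, the classic redox-ladder view of
#' an aquatic system: a couple's oxidized member can oxidize the reduced
#' member of any couple below it. One reduced species is designated the
#' electron reference level - the zero of the electron-equivalent scale used
#' by the oxidative-capacity calculation (ammonium for nitrification,
#' bisulphide for sulfur-driven denitrification).
#'
#' @param half_reactions Data.frame of half-reactions
#'   (see [load_half_reactions()]).
#' @param ph pH of the system.
#' @param temperature_k Absolute temperature (K).
#' @param reference_species Identifier of the reduced species serving as the
#'   electron reference level; must appear as `reduced` in at least one
#'   couple.
#' @param constants Physical constants.
#' @return An object of class `redox_ladder`: the half-reaction table with an
#'   `e_h_v` column, sorted by `e_h_v` descending, with attributes `ph`,
#'   `temperature_k` and `reference_species`.
#' @examples
#' hr <- load_half_reactions("nitrification")
#' build_ladder(hr, ph = 7.5, temperature_k = 296.15,
#'              reference_species = "NH4+")
#' @export
build_ladder <- function(half_reactions, ph, temperature_k,
                         reference_species,
                         constants = physical_constants()) {
  if (!reference_species %in% half_reactions$reduced)
    stop("reference species ", reference_species,
         " is not the reduced member of any couple")
  eh <- half_potential(half_reactions, ph, temperature_k, constants)
  out <- half_reactions
  out$e_h_v <- eh
  out <- out[order(-out$e_h_v, out$id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("redox_ladder", "data.frame"),
            ph = ph, temperature_k = temperature_k,
            reference_species = reference_species)
}

#' @export
print.redox_ladder <- function(x, ...) {
  cat(sprintf("Redox ladder at pH %.2f, T %.2f K (reference level: %s)\n",
              attr(x, "ph"), attr(x, "temperature_k"),
              attr(x, "reference_species")))
  df <- data.frame(couple = paste(x$oxidized, x$reduced, sep = "/"),
                   E_H_V = round(x$e_h_v, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Per-stage table of half-reaction potentials
#'
#' Evaluates every couple's pH-corrected potential under each reactor stage's
#' conditions, one row per stage and one column per couple.
#'
#' The temperature policy controls which temperature enters the Nernstian
#' slope: `"stage"` uses each stage's recorded operational temperature;
#' `"standard"` uses a fixed temperature (default 298.15 K) for all stages.
#'
#' @param stages Data.frame with columns `stage_id`, `ph` and (for the
#'   `"stage"` policy) `temperature_c`.
#' @param half_reactions Data.frame of half-reactions.
#' @param temperature_policy `"stage"` or `"standard"`.
#' @param standard_temperature_k Temperature used under the `"standard"`
#'   policy.
#' @param constants Physical constants.
#' @param decadic_slope_v Optional fixed Nernst slope (V per pH unit); see
#'   [half_potential()].
#' @return Data.frame: `stage_id`, `ph`, `temperature_k`, then one E_H column
#'   per couple (named by couple id, volts).
#' @export
potentials_table <- function(stages, half_reactions,
                             temperature_policy = c("stage", "standard"),
                             standard_temperature_k = 298.15,
                             constants = physical_constants(),
                             decadic_slope_v = NULL) {
  temperature_policy <- match.arg(temperature_policy)
  if (!nrow(stages)) {
    out <- data.frame(stage_id = character(), ph = numeric(),
                      temperature_k = numeric())
    for (id in half_reactions$id) out[[id]] <- numeric()
    return(out)
  }
  temp_k <- if (temperature_policy == "stage") {
    stages$temperature_c + 273.15
  } else {
    rep(standard_temperature_k, nrow(stages))
  }
  out <- data.frame(stage_id = stages$stage_id, ph = stages$ph,
                    temperature_k = temp_k, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(half_reactions))) {
    out[[half_reactions$id[k]]] <-
      half_potential(half_reactions[k, ], stages$ph, temp_k, constants,
                     decadic_slope_v)
  }
  rownames(out) <- NULL
  out
}
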