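#' Bench-scale nitrification and autotrophic denitrification stage records
#'
#' Loads the embedded data set of reactor operating conditions: 12
#' nitrification stages from a nitrifying biofilm airlift suspended reactor
#' (three fixed liquid compositions, each probed at dissolved-oxygen levels
#' 0.5, 1, 2 and 5 mg O2/L in quick-change assays) and 9 stages of a
#' sulphide/nitrate sequencing batch reactor. Concentrations are in mg of
#' the basis element per liter (mg N/L, mg S/L; DO as mg O2/L); specific
#' production rates are biomass-normalized (per g VSS per day). Nitrous
#' oxide production is stored in the unit the source records carry
#' (g N2O-N/g VSS d); its magnitude suggests mg, but the unit never affects
#' the regression R^2 or p-values. Two denitrification stages never reached
#' stable operation (`stable = FALSE`) and are excluded from all
#' regressions.
#'
#' @param process Optional filter: `"nitrification"` or `"denitrification"`.
#' @return A data.frame, one row per stage, with columns `process`,
#'   `stage_id`, `ph`, `temperature_c`, influent/effluent concentrations
#'   (`nh4_n_i`, `nh4_n_e`, `no2_n_e`, `no3_n_i`, `no3_n_e`, `do_mg_l`,
#'   `s2_s_i`, `s2_s_e`, `so4_s_e`), production rates (`n2o_prod`,
#'   `s0_prod`, `no2_prod`) and `stable`.
#' @examples
#' stages <- load_study_data()
#' table(stages$process)
#' @export
load_study_data <- function(process = NULL) {
  path <- system.file("extdata", "study_stages.csv", package = "oxcap",
                      mustWork = TRUE)
  d <- read_stage_csv(path)
  if (!is.null(process)) {
    process <- match.arg(process, c("nitrification", "denitrification"))
    d <- d[d$process == process, , drop = FALSE]
    rownames(d) <- NULL
  }
  d
}

.stage_columns <- c("process", "stage_id", "ph", "temperature_c",
                    "nh4_n_i", "nh4_n_e", "no2_n_e", "no3_n_i", "no3_n_e",
                    "do_mg_l", "s2_s_i", "s2_s_e", "so4_s_e",
                    "n2o_prod", "s0_prod", "no2_prod", "stable")

#' Read or write stage records in the package's CSV schema
#'
#' One row per reactor stage; blank cells are allowed for columns that do not
#' apply to a process (e.g. sulfur columns for nitrification stages).
#'
#' @param path File path.
#' @return `read_stage_csv`: a validated data.frame of stage records.
#' @export
read_stage_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.stage_columns, names(d))
  if (length(missing))
    stop("stage CSV ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  bad <- !d$process %in% c("nitrification", "denitrification")
  if (any(bad))
    stop("unknown process in row(s) ", paste(which(bad), collapse = ", "),
         ": ", paste(unique(d$process[bad]), collapse = ", "))
  d$stable <- as.logical(d$stable)
  d
}

#' @rdname read_stage_csv
#' @param stages Data.frame of stage records.
#' @return `write_stage_csv`: the path, invisibly.
#' @export
write_stage_csv <- function(stages, path) {
  missing <- setdiff(.stage_columns, names(stages))
  if (length(missing))
    stop("stage data is missing required column(s): ",
         paste(missing, collapse = ", "))
  utils::write.csv(stages[, .stage_columns], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Normalize a raw production rate by biomass
#'
#' Converts a bulk production rate into a biomass-specific rate by dividing
#' by the volatile suspended solids (VSS) mass.
#'
#' @param raw_production Production rate (e.g. mg/d). Vectorized.
#' @param vss_mass Biomass as VSS (g); must be positive.
#' @return Specific rate per g VSS per day.
#' @examples
#' normalize_by_biomass(10, 2)  # 5
#' @export
normalize_by_biomass <- function(raw_production, vss_mass) {
  if (any(!is.finite(vss_mass)) || any(vss_mass <= 0))
    stop("VSS mass must be positive")
  raw_production / vss_mass
}

#' Oxidative capacity of each study stage
#'
#' Applies the process presets to the stage records: nitrification uses the
#' tested dissolved oxygen and the effluent nitrite of the stage's parent
#' composition block; denitrification uses effluent nitrate, nitrite and
#' sulfate (the bulk liquid at steady state).
#'
#' @param stages Stage records, as from [load_study_data()].
#' @return The input with an `oxc` column (eq/L; NA for unstable stages with
#'   no effluent data).
#' @export
stage_oxc <- function(stages) {
  oxc <- rep(NA_real_, nrow(stages))
  ni <- stages$process == "nitrification"
  de <- stages$process == "denitrification" & stages$stable
  if (any(ni))
    oxc[ni] <- nitrification_oxc(stages$do_mg_l[ni], stages$no2_n_e[ni])
  if (any(de))
    oxc[de] <- denitrification_oxc(stages$no3_n_e[de], stages$no2_n_e[de],
                                   stages$so4_s_e[de])
  stages$oxc <- oxc
  stages
}

#' Per-stage half-reaction potentials for the study data
#'
#' Recomputes the per-stage redox-ladder potentials: the three ammonia-
#' oxidation couples for each nitrification stage and the four
#' denitrification couples for each denitrification stage.
#'
#' Three policies are offered. The tabulated study potentials were compiled
#' with the conventional handbook Nernst slope of 0.059 V per pH unit
#' (2.303 R T / F rounded to two significant figures near 25 C): under the
#' default `"study"` policy, which applies that slope to all stages, every
#' tabulated cell is recovered to two-decimal precision. `"standard"`
#' computes the slope from the physical constants at 298.15 K; `"stage"`
#' does so at each stage's recorded operational temperature. The tabulated
#' denitrification potentials do not correspond to the reactor's 30 C: at
#' 303.15 K the NO3-/N2 couple at pH 7.7 gives 0.69 V, not the tabulated
#' 0.70 V, whereas 298.15 K recovers the example cells.
#'
#' @param temperature_policy `"study"`, `"stage"` or `"standard"`.
#' @param constants Physical constants.
#' @return A list with data.frames `nitrification` and `denitrification`,
#'   one row per stage and one potential column (volts) per couple.
#' @examples
#' t4 <- reproduce_table4()
#' round(t4$nitrification$o2_h2o, 2)   # 0.79 for every stage
#' @export
reproduce_table4 <- function(temperature_policy = c("study", "stage",
                                                    "standard"),
                             constants = physical_constants()) {
  temperature_policy <- match.arg(temperature_policy)
  out <- lapply(c(nitrification = "nitrification",
                  denitrification = "denitrification"), function(p) {
    st <- load_study_data(p)
    hr <- load_half_reactions(p)
    pol <- if (temperature_policy == "stage") "stage" else "standard"
    slope <- if (temperature_policy == "study") 0.059 else NULL
    potentials_table(st, hr, temperature_policy = pol,
                     constants = constants, decadic_slope_v = slope)
  })
  out
}

#' Oxidative-capacity regressions of the study data
#'
#' Fits the three simple linear regressions of biomass-specific intermediate
#' production on bulk-liquid oxidative capacity: nitrous oxide over the 12
#' nitrification stages, and elemental sulfur and nitrite over the 7 stable
#' denitrification stages. Unstable stages are excluded.
#'
#' @param level Level for the accompanying confidence/prediction bands.
#' @return A named list of three [oxc_lm()] fits (`n2o`, `s0`, `no2`), each
#'   with attributes `confidence_band` and `prediction_band` evaluated over
#'   the observed OXC range.
#' @examples
#' reg <- reproduce_regressions()
#' reg$n2o
#' @export
reproduce_regressions <- function(level = 0.95) {
  d <- stage_oxc(load_study_data())
  ni <- d[d$process == "nitrification", ]
  de <- d[d$process == "denitrification" & d$stable, ]
  fits <- list(
    n2o = oxc_lm(n2o_prod ~ oxc, data = ni),
    s0  = oxc_lm(s0_prod ~ oxc, data = de),
    no2 = oxc_lm(no2_prod ~ oxc, data = de)
  )
  lapply(fits, function(f) {
    xs <- seq(min(f$model$x), max(f$model$x), length.out = 50)
    attr(f, "confidence_band") <- confidence_band(f, xs, level)
    attr(f, "prediction_band") <- prediction_band(f, xs, level)
    f
  })
}

#' Per-stage Gibbs free energy per electron for the candidate reactions
#'
#' Evaluates the Gibbs free energy per mole of electrons of every applicable
#' candidate reaction under each stage's bulk-liquid conditions (effluent
#' concentrations, stage pH and operational temperature): the two ammonia-
#' oxidation reactions for nitrification stages, the six sulfur/nitrogen
#' reactions for stable denitrification stages. Residual effluent sulphide
#' (reported as S2--S) supplies the bisulphide activity one-to-one on the
#' sulfur basis; unmeasured dissolved gases (N2, N2O) enter at unit
#' activity unless overridden.
#'
#' @param activity_overrides Optional named list of molar activities
#'   forwarded to [delta_g_per_electron()].
#' @param constants Physical constants.
#' @return A list of two matrices (`nitrification`, `denitrification`),
#'   stages in rows, reactions in columns, kJ per mol e-.
#' @export
reproduce_fig2_inputs <- function(activity_overrides = NULL,
                                  constants = physical_constants()) {
  rxn <- load_reactions()
  ni <- load_study_data("nitrification")
  ni_r <- rxn[c("i", "ii")]
  ni_m <- t(vapply(seq_len(nrow(ni)), function(k) {
    st <- stage_state(ni$ph[k], ni$temperature_c[k] + 273.15,
                      c("NH4+" = ni$nh4_n_e[k], "NO2-" = ni$no2_n_e[k],
                        "O2" = ni$do_mg_l[k]))
    vapply(ni_r, delta_g_per_electron, numeric(1), state = st,
           activity_overrides = activity_overrides, constants = constants)
  }, numeric(length(ni_r))))
  rownames(ni_m) <- paste0("stage_", ni$stage_id)

  de <- load_study_data("denitrification")
  de <- de[de$stable, , drop = FALSE]
  de_r <- rxn[c("iii", "iv", "v", "vi", "vii", "viii")]
  de_m <- t(vapply(seq_len(nrow(de)), function(k) {
    st <- stage_state(de$ph[k], de$temperature_c[k] + 273.15,
                      c("HS-" = de$s2_s_e[k], "NO2-" = de$no2_n_e[k],
                        "NO3-" = de$no3_n_e[k], "SO4-2" = de$so4_s_e[k]))
    vapply(de_r, delta_g_per_electron, numeric(1), state = st,
           activity_overrides = activity_overrides, constants = constants)
  }, numeric(length(de_r))))
  rownames(de_m) <- paste0("stage_", de$stage_id)

  list(nitrification = ni_m, denitrification = de_m)
}

#' Reproduce all computed study artifacts to disk
#'
#' One-call reporting entry point: writes the per-stage half-reaction
#' potentials (`table4.csv`), the per-stage oxidative capacities
#' (`oxc_per_stage.csv`), the three regression summaries with their bands
#' (`regressions.json`) and the per-stage Gibbs free energies per electron
#' (`gibbs_per_electron.csv`) into a directory, and returns the computed
#' objects invisibly. The constants and conventions used (gas constant,
#' Faraday constant, temperature policy, unit gas activities) are embedded
#' in the JSON report for auditability.
#'
#' @param dir Output directory (created if needed).
#' @param temperature_policy Passed to [reproduce_table4()].
#' @param level Band level for the regressions.
#' @param constants Physical constants.
#' @return Invisibly, a list with elements `potentials`, `oxc`,
#'   `regressions` and `gibbs`.
#' @export
reproduce_study <- function(dir = ".", temperature_policy = "study",
                            level = 0.95,
                            constants = physical_constants()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pots <- reproduce_table4(temperature_policy, constants)
  pot_long <- do.call(rbind, lapply(names(pots), function(p) {
    tab <- pots[[p]]
    couples <- setdiff(names(tab), c("stage_id", "ph", "temperature_k"))
    do.call(rbind, lapply(couples, function(cp) {
      data.frame(process = p, stage_id = tab$stage_id, ph = tab$ph,
                 temperature_k = tab$temperature_k, couple = cp,
                 e_h_v = tab[[cp]], row.names = NULL)
    }))
  }))
  utils::write.csv(pot_long, file.path(dir, "table4.csv"), row.names = FALSE)

  oxc <- stage_oxc(load_study_data())
  utils::write.csv(oxc[, c("process", "stage_id", "oxc")],
                   file.path(dir, "oxc_per_stage.csv"), row.names = FALSE)

  reg <- reproduce_regressions(level)
  reg_json <- lapply(reg, function(f) list(
    response = f$yname, n = f$n,
    slope = f$slope, intercept = f$intercept,
    r_squared = f$r_squared, f_statistic = f$f_statistic,
    p_value = f$p_value, sigma = f$sigma,
    confidence_band = attr(f, "confidence_band"),
    prediction_band = attr(f, "prediction_band")
  ))
  report <- list(
    config = list(R_kJ_per_mol_K = constants$R_kJ,
                  faraday_C_per_mol = constants$faraday,
                  temperature_policy = temperature_policy,
                  band_level = level,
                  gas_activity_default = 1),
    regressions = reg_json
  )
  jsonlite::write_json(report, file.path(dir, "regressions.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")

  gibbs <- reproduce_fig2_inputs(constants = constants)
  long_g <- function(m, process) {
    data.frame(process = process,
               stage = rep(rownames(m), times = ncol(m)),
               reaction = rep(colnames(m), each = nrow(m)),
               dg_per_e_kj = as.vector(m), row.names = NULL)
  }
  gl <- rbind(long_g(gibbs$nitrification, "nitrification"),
              long_g(gibbs$denitrification, "denitrification"))
  utils::write.csv(gl, file.path(dir, "gibbs_per_electron.csv"),
                   row.names = FALSE)

  invisible(list(potentials = pots, oxc = oxc, regressions = reg,
                 gibbs = gibbs))
}
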