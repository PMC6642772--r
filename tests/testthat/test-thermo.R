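test_that("shipped reactions balance in elements and charge", {
  rxns <- load_reactions()
  expect_length(rxns, 8)
  expect_equal(names(rxns), c("i", "ii", "iii", "iv", "v", "vi", "vii",
                              "viii"))
  for (r in rxns)
    expect_equal(unname(reaction_balance(r)), rep(0, 5), label = r$id)
  # quotient exponents match the stoichiometry of the non-unit-activity
  # species
  reg <- species_registry()
  for (r in rxns) {
    solids <- reg$identifier[reg$phase %in% c("solid", "solvent")]
    expected <- r$stoichiometry[setdiff(names(r$stoichiometry), solids)]
    expect_equal(r$quotient[names(expected)], expected, label = r$id)
  }
})

test_that("reaction quotient evaluates the printed activity products", {
  rxn <- load_reactions()
  # all activities 1 -> Q = 1
  st <- stage_state(0, 298.15)
  ov <- list("NO2-" = 1, "NH4+" = 1, "O2" = 1)
  expect_equal(reaction_quotient(rxn[["i"]], st, ov), 1)
  # hand evaluation: [NO2-]=[NH4+]=[O2]=1e-3 M, pH 7
  st <- stage_state(7, 298.15,
                    c("NO2-" = 14, "NH4+" = 14, "O2" = 32))
  q <- reaction_quotient(rxn[["i"]], st)
  expect_equal(q, (1e-3 * 1e-14) / (1e-3 * (1e-3)^1.5), tolerance = 1e-12)
  expect_equal(q, 3.1623e-10, tolerance = 1e-4)
  # unmeasured N2 enters at unit activity
  st_d <- stage_state(8, 303.15, c("HS-" = 32, "NO3-" = 14, "SO4-2" = 32,
                                   "NO2-" = 14))
  q3 <- reaction_quotient(rxn[["iii"]], st_d)
  q3_override <- reaction_quotient(rxn[["iii"]], st_d, list(N2 = 1))
  expect_equal(q3, q3_override)
})

test_that("quotient errors and flooring behave as specified", {
  rxn <- load_reactions()[["i"]]
  st <- stage_state(7, 298.15, c("NO2-" = 14))  # NH4+, O2 missing
  expect_error(reaction_quotient(rxn, st), "NH4\\+|no concentration")
  st0 <- stage_state(7, 298.15, c("NO2-" = 14, "NH4+" = 0, "O2" = 32))
  expect_warning(q <- reaction_quotient(rxn, st0), "floored")
  expect_true(is.finite(q))
  expect_error(
    reaction_quotient(rxn, st0, list("NH4+" = 0)),
    "positive"
  )
})

test_that("delta_g returns the standard value at Q = 1 for all reactions", {
  rxns <- load_reactions()
  st <- stage_state(7, 298.15)
  unit <- list("NO2-" = 1, "NH4+" = 1, "O2" = 1, "HS-" = 1, "NO3-" = 1,
               "SO4-2" = 1, "N2" = 1, "N2O" = 1, "H+" = 1)
  dg0 <- c(i = -273.0, ii = -526.6, iii = -990.1, iv = -3726.9, v = -136.6,
           vi = -499.7, vii = -2736.8, viii = -414.9)
  ne <- c(i = 6, ii = 8, iii = 10, iv = 40, v = 2, vi = 8, vii = 30,
          viii = 6)
  for (id in names(rxns)) {
    expect_equal(delta_g(rxns[[id]], st, unit), dg0[[id]], label = id)
    expect_equal(delta_g_per_electron(rxns[[id]], st, unit),
                 dg0[[id]] / ne[[id]], label = id)
  }
  expect_equal(delta_g_per_electron(rxns[["i"]], st, unit), -45.5)
  expect_equal(delta_g_per_electron(rxns[["ii"]], st, unit), -65.825)
  expect_equal(delta_g_per_electron(rxns[["vii"]], st, unit), -2736.8 / 30)
})

test_that("delta_g matches the frozen brute-force value at stage 9", {
  # nitrification stage 9 effluent: NH4+ 9, NO2- 3, DO 0.5 mg/L, pH 7.5,
  # 296.15 K; oracle evaluated dG0 + RT ln Q by hand
  rxn <- load_reactions()[["i"]]
  st <- stage_state(7.5, 296.15, c("NH4+" = 9, "NO2-" = 3, "O2" = 0.5))
  expect_equal(delta_g(rxn, st), -319.873793519934, tolerance = 1e-10)
  expect_equal(delta_g_per_electron(rxn, st), -53.3122989199889,
               tolerance = 1e-10)
  rxn2 <- load_reactions()[["ii"]]
  expect_equal(delta_g_per_electron(rxn2, st), -65.1190663000763,
               tolerance = 1e-10)
})

test_that("delta_g is monotone in product and reactant activities", {
  rxn <- load_reactions()[["i"]]
  st <- stage_state(7.5, 296.15, c("NH4+" = 9, "NO2-" = 3, "O2" = 0.5))
  base <- delta_g(rxn, st)
  up_product <- delta_g(rxn, st, list("NO2-" = 10 * to_molar("NO2-", 3)))
  expect_gt(up_product, base)
  up_reactant <- delta_g(rxn, st, list("NH4+" = 10 * to_molar("NH4+", 9)))
  expect_lt(up_reactant, base)
  # per-electron value times electrons recovers the total
  expect_equal(delta_g_per_electron(rxn, st) * rxn$electrons,
               delta_g(rxn, st), tolerance = 1e-12)
})

test_that("ranking orders reactions by dG per electron, stably", {
  rxns <- load_reactions()
  st <- stage_state(7, 298.15)
  unit <- list("NO2-" = 1, "NH4+" = 1, "O2" = 1, "N2O" = 1)
  rk <- rank_reactions(rxns[c("i", "ii")], st, unit)
  expect_equal(rk$id, c("ii", "i"))  # -65.825 < -45.5
  one <- rank_reactions(rxns["i"], st, unit)
  expect_equal(one$id, "i")
  # denitrification stage 2 state: full ordering from the frozen oracle
  st2 <- stage_state(8.0, 303.15, c("HS-" = 0.9, "NO2-" = 110,
                                    "NO3-" = 294, "SO4-2" = 205))
  rk2 <- rank_reactions(rxns[c("iii", "iv", "v", "vi", "vii", "viii")], st2)
  expect_equal(rk2$id, c("vii", "viii", "iv", "vi", "iii", "v"))
  expect_error(rank_reactions(list(), st), "at least one")
})
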