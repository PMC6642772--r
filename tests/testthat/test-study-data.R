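test_that("embedded stage records have the expected shape and key cells", {
  d <- load_study_data()
  expect_equal(sum(d$process == "nitrification"), 12)
  expect_equal(sum(d$process == "denitrification"), 9)
  s1 <- d[d$process == "nitrification" & d$stage_id == 1, ]
  expect_equal(s1$nh4_n_i, 500)
  expect_equal(s1$no2_n_e, 170)
  expect_equal(s1$do_mg_l, 0.5)
  expect_equal(s1$n2o_prod, 10.6)
  d6 <- d[d$process == "denitrification" & d$stage_id == 6, ]
  expect_equal(d6$s0_prod, -13.0)  # net consumption of accumulated sulfur
  # the two stages that never stabilized are flagged and carry no effluent
  unstable <- d[d$process == "denitrification" & d$stage_id %in% c(1, 5), ]
  expect_false(any(unstable$stable))
  expect_true(all(is.na(unstable$no3_n_e)))
})

test_that("fixture integrity: checksum over all numeric cells", {
  d <- load_study_data()
  num <- unlist(d[vapply(d, is.numeric, TRUE)])
  # hand-added from the source table: 12058.2 (nitrification rows incl.
  # stage ids) + 9599.2 (stable denitrification) + 1281.3 (unstable)
  expect_equal(sum(num, na.rm = TRUE), 22938.7, tolerance = 1e-9)
  expect_equal(sum(!is.na(num)), 12 * 9 + 7 * 11 + 2 * 5)
})

test_that("biomass normalization divides by VSS and rejects nonpositive", {
  expect_equal(normalize_by_biomass(10, 2), 5)
  expect_equal(normalize_by_biomass(0, 3), 0)
  expect_equal(normalize_by_biomass(7.5, 3), 2.5)
  expect_error(normalize_by_biomass(1, 0), "positive")
  expect_error(normalize_by_biomass(1, -2), "positive")
})

test_that("stage CSV round-trips and validates its schema", {
  d <- load_study_data()
  tmp <- tempfile(fileext = ".csv")
  write_stage_csv(d, tmp)
  d2 <- read_stage_csv(tmp)
  expect_equal(d2, d)
  bad <- tempfile(fileext = ".csv")
  write.csv(d[, -which(names(d) == "no2_n_e")], bad, row.names = FALSE)
  expect_error(read_stage_csv(bad), "no2_n_e")
})

test_that("per-stage OXC uses the process presets on the right columns", {
  d <- stage_oxc(load_study_data())
  ni <- d[d$process == "nitrification", ]
  expect_equal(ni$oxc[ni$stage_id == 1], 0.0729821, tolerance = 1e-5)
  de <- d[d$process == "denitrification", ]
  expect_equal(de$oxc[de$stage_id == 2], 0.1798214, tolerance = 1e-5)
  expect_true(all(is.na(de$oxc[de$stage_id %in% c(1, 5)])))
})

test_that("per-stage potentials reproduce the tabulated values", {
  t4 <- reproduce_table4()  # default study policy
  ni <- t4$nitrification
  expect_equal(round(ni$n2o_nh4, 2), rep(1.49, 12))
  expect_equal(round(ni$o2_h2o, 2), rep(0.79, 12))
  expect_equal(round(ni$no2_nh4, 2), rep(0.30, 12))
  de <- t4$denitrification
  expect_equal(round(unlist(de[de$stage_id == 2,
                               c("no3_n2", "no2_n2", "so4_hs", "s_hs")]),
                     2),
               c(no3_n2 = 0.68, no2_n2 = -0.21, so4_hs = -0.28,
                 s_hs = -0.35))
  expect_equal(round(unlist(de[de$stage_id == 8,
                               c("no3_n2", "no2_n2", "so4_hs", "s_hs")]),
                     2),
               c(no3_n2 = 0.70, no2_n2 = -0.19, so4_hs = -0.26,
                 s_hs = -0.34))
})

test_that("study regressions: counts, signs, significance, oracle values", {
  reg <- reproduce_regressions()
  expect_named(reg, c("n2o", "s0", "no2"))
  expect_equal(reg$n2o$n, 12)
  expect_equal(reg$s0$n, 7)
  expect_equal(reg$no2$n, 7)
  expect_true(all(vapply(reg, `[[`, 0, "p_value") < 0.05))
  expect_gt(reg$n2o$slope, 0)
  expect_lt(reg$s0$slope, 0)
  expect_gt(reg$no2$slope, 0)
  # frozen normal-equations oracle values
  expect_equal(reg$n2o$slope, 168.593096119026, tolerance = 1e-10)
  expect_equal(reg$n2o$intercept, 0.967818115881468, tolerance = 1e-9)
  expect_equal(reg$n2o$r_squared, 0.782521592127923, tolerance = 1e-10)
  expect_equal(reg$s0$slope, -697.778762530533, tolerance = 1e-10)
  expect_equal(reg$s0$r_squared, 0.970099974080915, tolerance = 1e-10)
  expect_equal(reg$no2$slope, 235.02652435779586, tolerance = 1e-10)
  expect_equal(reg$no2$r_squared, 0.777976577014065, tolerance = 1e-10)
  # attached bands nest
  for (f in reg) {
    cb <- attr(f, "confidence_band")
    pb <- attr(f, "prediction_band")
    expect_true(all(pb$lwr < cb$lwr) && all(pb$upr > cb$upr))
  }
})

test_that("per-stage Gibbs energies reproduce the expected orderings", {
  g <- reproduce_fig2_inputs()
  expect_equal(dim(g$nitrification), c(12L, 2L))
  expect_equal(dim(g$denitrification), c(7L, 6L))
  # ammonia -> N2O beats ammonia -> nitrite per electron at every stage
  expect_true(all(g$nitrification[, "ii"] < g$nitrification[, "i"]))
  # sulfur-consuming reactions beat sulfur-producing ones at every stage
  expect_true(all(apply(g$denitrification, 1, function(r)
    max(r[c("vii", "viii")]) < min(r[c("iii", "v")]))))
})

test_that("reproduce_study writes the full artifact set", {
  dir <- tempfile("report")
  out <- reproduce_study(dir)
  expect_true(all(file.exists(file.path(
    dir, c("table4.csv", "oxc_per_stage.csv", "regressions.json",
           "gibbs_per_electron.csv")))))
  rep <- jsonlite::fromJSON(file.path(dir, "regressions.json"))
  expect_equal(rep$config$faraday_C_per_mol, 96485)
  expect_equal(rep$regressions$n2o$n, 12)
  t4 <- read.csv(file.path(dir, "table4.csv"))
  expect_equal(nrow(t4), 12 * 3 + 9 * 4)
})
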