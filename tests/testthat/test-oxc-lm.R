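test_that("closed-form example: slope 1/2, intercept 1/6, R2 3/4, p 1/3", {
  fit <- oxc_lm(x = c(0, 1, 2), y = c(0, 1, 1))
  expect_equal(fit$slope, 0.5)
  expect_equal(fit$intercept, 1 / 6)
  expect_equal(fit$r_squared, 0.75)
  expect_equal(fit$f_statistic, 3)
  expect_equal(fit$p_value, 1 / 3)  # two-sided t on 1 df: 2*(1 - P(t < sqrt(3)))
  expect_equal(unname(coef(fit)), c(1 / 6, 0.5))

  perfect <- oxc_lm(x = c(0, 1, 2), y = c(1, 3, 5))
  expect_equal(perfect$slope, 2)
  expect_equal(perfect$intercept, 1)
  expect_equal(perfect$r_squared, 1)
})

test_that("fit agrees with the normal-equations oracle on random inputs", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(4:40, 1)
    x <- runif(n, 0, 10)
    y <- runif(1, -5, 5) + runif(1, -3, 3) * x + rnorm(n)
    o <- ols_oracle(x, y)
    fit <- oxc_lm(x = x, y = y)
    expect_equal(fit$slope, o$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(fit$r_squared, o$r_squared, tolerance = 1e-10)
    expect_equal(fit$f_statistic, o$f_statistic, tolerance = 1e-10)
    expect_equal(fit$p_value, o$p_value, tolerance = 1e-10)
    expect_equal(fit$sigma, o$sigma, tolerance = 1e-10)
    expect_equal(sum(residuals(fit)), 0, tolerance = 1e-8)
  }
})

test_that("R2 is invariant under affine rescaling of the predictor", {
  set.seed(32)
  x <- runif(15); y <- 2 * x + rnorm(15, 0, 0.3)
  r2 <- oxc_lm(x = x, y = y)$r_squared
  expect_equal(oxc_lm(x = 1000 * x + 7, y = y)$r_squared, r2,
               tolerance = 1e-12)
})

test_that("p-value decreases as R2 increases at fixed n", {
  # same x, responses with increasing signal-to-noise
  set.seed(33)
  x <- seq(0, 1, length.out = 10)
  e <- rnorm(10)
  fits <- lapply(c(0.5, 2, 8), function(b) oxc_lm(x = x, y = b * x + e))
  r2 <- vapply(fits, `[[`, 0, "r_squared")
  p <- vapply(fits, `[[`, 0, "p_value")
  expect_true(all(diff(r2) > 0))
  expect_true(all(diff(p) < 0))
})

test_that("degenerate designs are rejected", {
  expect_error(oxc_lm(x = c(1, 1, 1), y = c(1, 2, 3)), "degenerate")
  expect_error(oxc_lm(x = c(1, 2), y = c(1, 2)), "at least 3")
  expect_error(oxc_lm(x = 1:3, y = 1:4), "equal length")
})

test_that("bands match the closed-form oracle and nest properly", {
  x <- c(0, 1, 2); y <- c(0, 1, 1)
  fit <- oxc_lm(x = x, y = y)
  o <- ols_oracle(x, y)
  cb <- confidence_band(fit, 1)
  pb <- prediction_band(fit, 1)
  # hand values: t(0.975, 1) = 12.706..., s*sqrt(1/3), s*sqrt(4/3)
  expect_equal(cb$fit, 2 / 3)
  expect_equal(cb$lwr, band_oracle(o, 1)$lwr, tolerance = 1e-10)
  expect_equal(cb$upr, band_oracle(o, 1)$upr, tolerance = 1e-10)
  expect_equal(pb$lwr, band_oracle(o, 1, kind = "prediction")$lwr,
               tolerance = 1e-10)
  expect_equal(pb$upr, band_oracle(o, 1, kind = "prediction")$upr,
               tolerance = 1e-10)

  # prediction band strictly contains confidence band on randomized inputs
  set.seed(34)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    xr <- runif(n); yr <- xr + rnorm(n, 0, 0.5)
    f <- oxc_lm(x = xr, y = yr)
    grid <- seq(-0.5, 1.5, length.out = 17)
    cbr <- confidence_band(f, grid)
    pbr <- prediction_band(f, grid)
    expect_true(all(pbr$lwr < cbr$lwr))
    expect_true(all(pbr$upr > cbr$upr))
    # band width minimal at the predictor mean
    w <- cbr$upr - cbr$lwr
    wbar <- confidence_band(f, mean(xr))
    expect_true(all(w >= (wbar$upr - wbar$lwr) - 1e-12))
  }

  # exact fit: zero-width bands
  pf <- oxc_lm(x = c(0, 1, 2), y = c(1, 3, 5))
  expect_equal(confidence_band(pf, c(0, 5))$lwr,
               confidence_band(pf, c(0, 5))$upr)
  expect_equal(prediction_band(pf, 0.5)$upr - prediction_band(pf, 0.5)$lwr, 0)
  expect_error(confidence_band(fit, 1, level = 1.2), "level")
})

test_that("standardized residuals use leverage; exact fit is 0 by convention", {
  fit <- oxc_lm(x = c(0, 1, 2), y = c(0, 1, 1))
  # oracle: h = (5/6, 1/3, 5/6), residuals (-1/6, 1/3, -1/6), s = sqrt(1/6)
  expect_equal(standardized_residuals(fit), c(-1, 1, -1), tolerance = 1e-12)
  expect_warning(sr <- standardized_residuals(
    oxc_lm(x = c(0, 1, 2), y = c(1, 3, 5))), "exact fit")
  expect_equal(sr, c(0, 0, 0))
})

test_that("methods: predict, simulate, confint, summary, plot", {
  d <- data.frame(oxc = c(0.01, 0.02, 0.05, 0.07, 0.1),
                  prod = c(1.2, 2.1, 4.9, 7.4, 9.8))
  fit <- oxc_lm(prod ~ oxc, data = d)
  expect_equal(fit$xname, "oxc")
  expect_equal(predict(fit), unname(fitted(fit)))
  expect_equal(predict(fit, newdata = data.frame(oxc = 0.05)),
               fit$intercept + fit$slope * 0.05)
  ci <- confint(fit)
  expect_equal(rownames(ci), c("intercept", "slope"))
  expect_true(ci["slope", 1] < fit$slope && fit$slope < ci["slope", 2])
  sim <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(5L, 3L))
  s <- summary(fit)
  expect_s3_class(s, "summary.oxc_lm")
  expect_output(print(s), "R\\^2")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})
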