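## Brute-force normal-equations oracle for simple OLS, independent of the
## lm-based implementation path.
ols_oracle <- function(x, y) {
  n <- length(x); xb <- mean(x); yb <- mean(y)
  Sxx <- sum((x - xb)^2); Sxy <- sum((x - xb) * (y - yb))
  Syy <- sum((y - yb)^2)
  b <- Sxy / Sxx; a <- yb - b * xb
  res <- y - (a + b * x); sse <- sum(res^2)
  r2 <- 1 - sse / Syy
  fstat <- r2 * (n - 2) / (1 - r2)
  list(slope = b, intercept = a, r_squared = r2, f_statistic = fstat,
       p_value = pf(fstat, 1, n - 2, lower.tail = FALSE),
       sigma = sqrt(sse / (n - 2)), n = n, xbar = xb, Sxx = Sxx,
       residuals = res)
}

## t-based band oracle from the closed-form expressions
band_oracle <- function(o, x0, level = 0.95, kind = "confidence") {
  tq <- qt(1 - (1 - level) / 2, o$n - 2)
  extra <- if (kind == "prediction") 1 else 0
  half <- tq * o$sigma * sqrt(extra + 1 / o$n + (x0 - o$xbar)^2 / o$Sxx)
  fit <- o$intercept + o$slope * x0
  data.frame(x = x0, fit = fit, lwr = fit - half, upr = fit + half)
}

## direct transcription of the printed OXC formulas
oxc_nitrif_direct <- function(do, no2) 4 * do / 16000 + 6 * no2 / 14000
oxc_denit_direct <- function(no3, no2, so4)
  5 * no3 / 14000 + 3 * no2 / 14000 + 8 * so4 / 32000
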