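#' Simple linear regression of intermediate production on oxidative capacity
#'
#' Fits the ordinary least-squares model `production = a + b * OXC + e`,
#' the working model relating a specific intermediate production rate (the
#' response, typically in mg or g per g VSS per day) to the oxidative
#' capacity of the bulk liquid (the single explanatory variable, eq/L).
#' Inference follows the classical simple-regression ANOVA: the F statistic
#' on (1, n-2) degrees of freedom, its two-sided p-value, and t-based
#' confidence and prediction bands.
#'
#' Either a formula with one right-hand-side variable plus `data`, or raw
#' `x`/`y` vectors, may be supplied.
#'
#' @param formula Model formula of the form `response ~ predictor`.
#' @param data Data.frame holding the formula's variables.
#' @param x,y Alternative interface: predictor and response vectors.
#' @return An object of class `oxc_lm`: a list with the underlying `lm` fit
#'   (`$lm`), `slope`, `intercept`, `r_squared`, `f_statistic`, `p_value`,
#'   `sigma` (residual standard error), `n`, `df_residual`, standard errors
#'   (`se_slope`, `se_intercept`), the model frame (`$model` with columns
#'   `x`, `y`) and the variable names.
#' @examples
#' fit <- oxc_lm(x = c(0, 1, 2), y = c(0, 1, 1))
#' coef(fit)
#' summary(fit)
#' @seealso [confidence_band()], [prediction_band()],
#'   [standardized_residuals()]
#' @export
oxc_lm <- function(formula = NULL, data = NULL, x = NULL, y = NULL) {
  if (!is.null(formula)) {
    mf <- stats::model.frame(formula, data = data)
    if (ncol(mf) != 2)
      stop("formula must have exactly one predictor")
    y <- mf[[1]]; x <- mf[[2]]
    ynm <- names(mf)[1]; xnm <- names(mf)[2]
  } else {
    if (is.null(x) || is.null(y))
      stop("supply either a formula with data, or x and y vectors")
    xnm <- "x"; ynm <- "y"
  }
  if (length(x) != length(y))
    stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3)
    stop("at least 3 complete observations are required for inference")
  if (max(x) - min(x) <= 0 || stats::sd(x) == 0)
    stop("degenerate design: the predictor is constant")

  d <- data.frame(x = x, y = y)
  fit <- stats::lm(y ~ x, data = d)
  # exact fits are legitimate here (zero-noise synthetic data); silence the
  # "essentially perfect fit" note
  sm <- suppressWarnings(summary(fit))
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst
  fstat <- if (r2 < 1) r2 * (n - 2) / (1 - r2) else Inf
  pval <- stats::pf(fstat, 1, n - 2, lower.tail = FALSE)

  structure(list(
    lm = fit,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    f_statistic = fstat,
    p_value = pval,
    sigma = sm$sigma,
    n = n,
    df_residual = n - 2,
    se_intercept = sm$coefficients[1, 2],
    se_slope = sm$coefficients[2, 2],
    model = d,
    xname = xnm, yname = ynm,
    call = match.call()
  ), class = "oxc_lm")
}

#' @export
print.oxc_lm <- function(x, digits = 4, ...) {
  cat("Oxidative-capacity regression:", x$yname, "~", x$xname, "\n")
  cat(sprintf("  slope     %s\n  intercept %s\n",
              format(x$slope, digits = digits),
              format(x$intercept, digits = digits)))
  cat(sprintf("  R^2 = %.3f, F(1, %d) = %s, p = %s, n = %d\n",
              x$r_squared, x$df_residual,
              format(x$f_statistic, digits = digits),
              format.pval(x$p_value, digits = digits), x$n))
  invisible(x)
}

#' @export
summary.oxc_lm <- function(object, ...) {
  sr <- tryCatch(standardized_residuals(object),
                 warning = function(w) standardized_residuals_quiet(object))
  structure(list(fit = object, std_residuals = sr,
                 coef_table = summary(object$lm)$coefficients),
            class = "summary.oxc_lm")
}

#' @export
print.summary.oxc_lm <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coef_table)
  cat(sprintf("\nResidual standard error: %s on %d degrees of freedom\n",
              format(x$fit$sigma, digits = 4), x$fit$df_residual))
  cat("Standardized residuals:\n")
  print(summary(x$std_residuals))
  invisible(x)
}

#' @export
coef.oxc_lm <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
vcov.oxc_lm <- function(object, ...) stats::vcov(object$lm)

#' @export
nobs.oxc_lm <- function(object, ...) object$n

#' @export
residuals.oxc_lm <- function(object, ...) stats::residuals(object$lm)

#' @export
fitted.oxc_lm <- function(object, ...) stats::fitted(object$lm)

#' @export
confint.oxc_lm <- function(object, parm, level = 0.95, ...) {
  ci <- suppressWarnings(stats::confint(object$lm, level = level))
  rownames(ci) <- c("intercept", "slope")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Predict from an oxidative-capacity regression
#'
#' @param object An [oxc_lm()] fit.
#' @param newdata Numeric vector of predictor values, or a data.frame with a
#'   column named after the fit's predictor (or `x`). Defaults to the
#'   observed predictor values.
#' @param interval `"none"`, `"confidence"` (mean response) or
#'   `"prediction"` (single new observation).
#' @param level Confidence level.
#' @param ... Unused.
#' @return Fitted values, or (with an interval) a data.frame with columns
#'   `fit`, `lwr`, `upr`.
#' @export
predict.oxc_lm <- function(object, newdata = NULL,
                           interval = c("none", "confidence", "prediction"),
                           level = 0.95, ...) {
  interval <- match.arg(interval)
  if (is.null(newdata)) {
    xv <- object$model$x
  } else if (is.data.frame(newdata)) {
    nm <- intersect(c(object$xname, "x"), names(newdata))
    if (!length(nm)) stop("newdata must contain column ", object$xname)
    xv <- newdata[[nm[1]]]
  } else {
    xv <- as.numeric(newdata)
  }
  nd <- data.frame(x = xv)
  if (interval == "none")
    return(unname(stats::predict(object$lm, newdata = nd)))
  p <- stats::predict(object$lm, newdata = nd, interval = interval,
                      level = level)
  out <- as.data.frame(p)
  rownames(out) <- NULL
  out
}

#' Confidence band for the mean response
#'
#' The pointwise t-based band for the regression mean at each abscissa:
#' `yhat +/- t(1-alpha/2, n-2) * s * sqrt(1/n + (x0-xbar)^2/Sxx)`. Narrowest
#' at the predictor mean; zero-width when the fit is exact.
#'
#' @param object An [oxc_lm()] fit.
#' @param abscissae Predictor values at which to evaluate the band; defaults
#'   to the observed values.
#' @param level Band level (default 0.95).
#' @return Data.frame with columns `x`, `fit`, `lwr`, `upr`; attributes
#'   `kind = "confidence"` and `level`.
#' @export
confidence_band <- function(object, abscissae = NULL, level = 0.95) {
  .band(object, abscissae, level, "confidence")
}

#' Prediction band for a single new observation
#'
#' As [confidence_band()] but with the extra unit variance term,
#' `sqrt(1 + 1/n + (x0-xbar)^2/Sxx)`: the range expected to contain an
#' individual new observation at the stated level. Strictly contains the
#' confidence band wherever the residual scatter is nonzero.
#'
#' @inheritParams confidence_band
#' @return Data.frame with columns `x`, `fit`, `lwr`, `upr`; attributes
#'   `kind = "prediction"` and `level`.
#' @export
prediction_band <- function(object, abscissae = NULL, level = 0.95) {
  .band(object, abscissae, level, "prediction")
}

.band <- function(object, abscissae, level, kind) {
  stopifnot(inherits(object, "oxc_lm"))
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("level must lie in (0, 1)")
  if (is.null(abscissae)) abscissae <- object$model$x
  p <- predict(object, newdata = abscissae, interval = kind, level = level)
  out <- data.frame(x = abscissae, fit = p$fit, lwr = p$lwr, upr = p$upr)
  attr(out, "kind") <- kind
  attr(out, "level") <- level
  out
}

#' Internally studentized residuals
#'
#' Each residual divided by `s * sqrt(1 - h_ii)`, with `h_ii` the leverage of
#' the point - the standard diagnostic for outlying observations in a simple
#' regression. For an exact fit (zero residual scatter) the values are all
#' zero by convention, with a warning; a leverage of 1 makes the residual
#' undefined and is an error.
#'
#' @param object An [oxc_lm()] fit.
#' @return Numeric vector of standardized residuals, one per observation.
#' @export
standardized_residuals <- function(object) {
  stopifnot(inherits(object, "oxc_lm"))
  if (.exact_fit(object)) {
    warning("exact fit: standardized residuals set to 0 by convention",
            call. = FALSE)
    return(rep(0, object$n))
  }
  h <- stats::hatvalues(object$lm)
  if (any(h >= 1 - 1e-12))
    stop("leverage of 1: standardized residual undefined")
  unname(stats::rstandard(object$lm))
}

standardized_residuals_quiet <- function(object) {
  suppressWarnings(standardized_residuals(object))
}

## residual scatter indistinguishable from floating-point noise
.exact_fit <- function(object) {
  scale <- max(abs(object$model$y), 1)
  object$sigma <= sqrt(.Machine$double.eps) * scale
}

#' Simulate responses from a fitted oxidative-capacity regression
#'
#' Draws new response vectors from the fitted Gaussian model at the observed
#' predictor values, via the underlying `lm` machinery.
#'
#' @param object An [oxc_lm()] fit.
#' @param nsim Number of response vectors.
#' @param seed Optional RNG seed (as in [stats::simulate()]).
#' @param ... Unused.
#' @return Data.frame of `nsim` simulated response columns.
#' @export
simulate.oxc_lm <- function(object, nsim = 1, seed = NULL, ...) {
  stats::simulate(object$lm, nsim = nsim, seed = seed, ...)
}

#' Plot an oxidative-capacity regression
#'
#' Scatter of the data with the fitted line and, optionally, the pointwise
#' confidence (dashed) and prediction (solid grey) bands.
#'
#' @param x An [oxc_lm()] fit.
#' @param bands Draw 95% confidence and prediction bands.
#' @param level Band level.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the fit.
#' @export
plot.oxc_lm <- function(x, bands = TRUE, level = 0.95, ...) {
  d <- x$model
  xs <- seq(min(d$x), max(d$x), length.out = 100)
  args <- list(...)
  if (is.null(args$xlab)) args$xlab <- x$xname
  if (is.null(args$ylab)) args$ylab <- x$yname
  pb <- prediction_band(x, xs, level)
  ylim <- if (bands && x$sigma > 0) range(d$y, pb$lwr, pb$upr) else range(d$y)
  if (is.null(args$ylim)) args$ylim <- ylim
  do.call(graphics::plot, c(list(d$x, d$y), args))
  graphics::abline(x$intercept, x$slope)
  if (bands && x$sigma > 0) {
    cb <- confidence_band(x, xs, level)
    graphics::lines(xs, cb$lwr, lty = 2, col = "grey40")
    graphics::lines(xs, cb$upr, lty = 2, col = "grey40")
    graphics::lines(xs, pb$lwr, lty = 1, col = "grey60")
    graphics::lines(xs, pb$upr, lty = 1, col = "grey60")
  }
  invisible(x)
}
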