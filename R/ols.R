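#' Ordinary least squares fit with the summary statistics used by band and
#' interval formulas
#'
#' Fits `y = intercept + slope * x` by ordinary least squares and returns the
#' quantities that the confidence/prediction band formulas and the
#' delta-method interval transforms consume directly: coefficient standard
#' errors, the residual standard deviation, the centred sum of squares of
#' `x`, and the Student-t quantile at `alpha/2` on `n - 2` degrees of
#' freedom.
#'
#' @param x numeric predictor; at least 3 values, at least 2 distinct.
#' @param y numeric response, same length as `x`.
#' @param alpha two-sided significance level for the stored t quantile
#'   (default 0.05, i.e. 95% intervals).
#' @return An object of class `"ols_fit"`: a list with components `slope`,
#'   `intercept`, `se_slope`, `se_intercept`, `resid_sd`, `sxx`
#'   (\eqn{\sum (x_i - \bar x)^2}), `x_mean`, `n`, `df`, `alpha`, `t_crit`,
#'   `fitted`, `residuals`, and the data `x`, `y`.
#' @seealso [confidence_band()], [prediction_band()], [fit_primary()],
#'   [fit_secondary()]
#' @examples
#' f <- ols_fit(0:4, c(1.1, 2.9, 5.2, 7.1, 8.8))
#' coef(f)
#' confidence_band(f, 2)
#' @export
ols_fit <- function(x, y, alpha = 0.05) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length", call. = FALSE)
  if (length(x) < 3L)
    stop("at least 3 points are required (got ", length(x), ")", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("'x' and 'y' must not contain missing values", call. = FALSE)
  if (length(unique(x)) < 2L)
    stop("degenerate design: all x values identical", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be a single value in (0, 1)", call. = FALSE)

  n <- length(x)
  x_mean <- mean(x)
  y_mean <- mean(y)
  xc <- x - x_mean
  sxx <- sum(xc^2)
  slope <- sum(xc * (y - y_mean)) / sxx
  intercept <- y_mean - slope * x_mean
  fitted <- intercept + slope * x
  res <- y - fitted
  df <- n - 2L
  resid_sd <- sqrt(sum(res^2) / df)
  se_slope <- resid_sd / sqrt(sxx)
  se_intercept <- resid_sd * sqrt(1 / n + x_mean^2 / sxx)
  t_crit <- stats::qt(1 - alpha / 2, df)

  structure(
    list(slope = slope, intercept = intercept,
         se_slope = se_slope, se_intercept = se_intercept,
         resid_sd = resid_sd, sxx = sxx, x_mean = x_mean,
         n = n, df = df, alpha = alpha, t_crit = t_crit,
         fitted = fitted, residuals = res, x = x, y = y),
    class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, digits = 4, ...) {
  cat("Least-squares line fit (", x$n, " points)\n", sep = "")
  cat("  intercept: ", format(x$intercept, digits = digits),
      "  (se ", format(x$se_intercept, digits = digits), ")\n", sep = "")
  cat("  slope:     ", format(x$slope, digits = digits),
      "  (se ", format(x$se_slope, digits = digits), ")\n", sep = "")
  cat("  residual sd: ", format(x$resid_sd, digits = digits),
      " on ", x$df, " degrees of freedom\n", sep = "")
  invisible(x)
}

#' @export
coef.ols_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.ols_fit <- function(object, ...) object$residuals

#' @export
predict.ols_fit <- function(object, x0 = object$x, ...) {
  object$intercept + object$slope * as.numeric(x0)
}

#' Confidence band half-width for the regression mean response
#'
#' Half-width of the two-sided `1 - alpha` interval for the expected value
#' of the response at `x0`:
#' \deqn{t_{\alpha/2}\,\sigma_y \sqrt{1/N + (x_0-\bar x)^2 / S_{xx}}}
#' The band is symmetric about the fitted value `predict(fit, x0)` and is
#' narrowest at \eqn{x_0 = \bar x}.
#'
#' @param fit an [ols_fit()] object.
#' @param x0 numeric vector of predictor values.
#' @return numeric vector of interval half-widths, one per `x0`.
#' @export
confidence_band <- function(fit, x0) {
  stopifnot(inherits(fit, "ols_fit"))
  x0 <- as.numeric(x0)
  fit$t_crit * fit$resid_sd * sqrt(1 / fit$n + (x0 - fit$x_mean)^2 / fit$sxx)
}

#' Prediction band half-width for a new observation
#'
#' Half-width of the two-sided `1 - alpha` interval for a single new
#' observation at `x0`:
#' \deqn{t_{\alpha/2}\,\sigma_y \sqrt{1 + 1/N + (x_0-\bar x)^2 / S_{xx}}}
#' Always at least as wide as the confidence band at the same `x0`.
#'
#' @inheritParams confidence_band
#' @return numeric vector of interval half-widths, one per `x0`.
#' @export
prediction_band <- function(fit, x0) {
  stopifnot(inherits(fit, "ols_fit"))
  x0 <- as.numeric(x0)
  fit$t_crit * fit$resid_sd * sqrt(1 + 1 / fit$n + (x0 - fit$x_mean)^2 / fit$sxx)
}
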