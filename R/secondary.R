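#' Table of per-temperature D-values with their 95% confidence half-widths
#'
#' The input to the secondary (Bigelow) model: one decimal reduction time per
#' temperature, each with the half-width of its 95% confidence interval (0 if
#' the uncertainty is to be ignored).
#'
#' @param temperature temperatures in degrees C; pairwise distinct, at
#'   least 3.
#' @param d_value D-values in minutes; strictly positive.
#' @param ci95_half 95% CI half-widths in minutes; non-negative. Recycled if
#'   a single value.
#' @return A data frame of class `"dt_table"` with columns `temperature`,
#'   `d_value`, `ci95_half`.
#' @seealso [fit_secondary()], [run_two_stage_mc()], [read_dt_table()],
#'   [carnitine_dt()]
#' @export
dt_table <- function(temperature, d_value, ci95_half = 0) {
  temperature <- as.numeric(temperature)
  d_value <- as.numeric(d_value)
  ci95_half <- rep_len(as.numeric(ci95_half), length(temperature))
  if (length(d_value) != length(temperature))
    stop("'temperature' and 'd_value' must have equal length", call. = FALSE)
  if (length(temperature) < 3L)
    stop("at least 3 temperatures are required", call. = FALSE)
  if (anyNA(temperature) || anyNA(d_value) || anyNA(ci95_half))
    stop("missing values are not allowed", call. = FALSE)
  if (anyDuplicated(temperature))
    stop("temperatures must be pairwise distinct", call. = FALSE)
  if (any(d_value <= 0))
    stop("D-values must be positive", call. = FALSE)
  if (any(ci95_half < 0))
    stop("CI half-widths must be non-negative", call. = FALSE)
  structure(
    data.frame(temperature = temperature, d_value = d_value,
               ci95_half = ci95_half),
    class = c("dt_table", "data.frame"))
}

#' Combine primary-model fits into a D-value table
#'
#' @param fits a list of [fit_primary()] results.
#' @return a [dt_table()].
#' @export
as_dt_table <- function(fits) {
  if (inherits(fits, "dt_fit")) fits <- list(fits)
  if (!length(fits) || !all(vapply(fits, inherits, logical(1), "dt_fit")))
    stop("'fits' must be a list of dt_fit objects", call. = FALSE)
  dt_table(vapply(fits, `[[`, numeric(1), "temperature"),
           vapply(fits, `[[`, numeric(1), "d_value"),
           vapply(fits, `[[`, numeric(1), "ci95_half"))
}

#' Fit the Bigelow secondary model
#'
#' Regresses `y = log10(D_T)` on `x = T_ref - T`. Under the Bigelow model
#' `log10 D_T = log10 D_Tref + (T_ref - T)/z`, so the slope is `1/z` and the
#' intercept is `log10 D_Tref`. Point estimates are `z = 1/slope` and
#' `D_Tref = 10^intercept`; their 95% half-widths come from the delta-method
#' transforms of the coefficient t-intervals:
#' `z^2 * t_crit * se_slope` and `ln(10) * D_Tref * t_crit * se_intercept`.
#'
#' For inactivation data D decreases with temperature, so the slope on
#' `T_ref - T` must be strictly positive; anything else is an error.
#'
#' @param table a [dt_table()] (the `ci95_half` column is not used by the
#'   deterministic fit; it feeds [run_two_stage_mc()]).
#' @param t_ref reference temperature in degrees C (default 120).
#' @param alpha two-sided significance level (default 0.05).
#' @return An object of class `"bigelow_fit"`: list with `t_ref`, `d_tref`
#'   (min), `d_tref_ci95_half`, `z` (degC), `z_ci95_half`, and `fit`, the
#'   underlying [ols_fit()] of log10 D on `T_ref - T`.
#' @examples
#' tab <- carnitine_dt("original")
#' fit <- fit_secondary(tab, t_ref = 120)
#' fit
#' coef(fit)
#' predict(fit, temperature = c(100, 115))
#' @export
fit_secondary <- function(table, t_ref = 120, alpha = 0.05) {
  if (!inherits(table, "dt_table"))
    stop("'table' must be a dt_table", call. = FALSE)
  if (!is.numeric(t_ref) || length(t_ref) != 1L || is.na(t_ref))
    stop("'t_ref' must be a single temperature", call. = FALSE)
  x <- t_ref - table$temperature
  y <- log10(table$d_value)
  fit <- ols_fit(x, y, alpha = alpha)
  if (fit$slope <= 0)
    stop("invalid temperature dependence: log10 D does not decrease with ",
         "temperature (slope on T_ref - T is ", format(fit$slope, digits = 4),
         ")", call. = FALSE)
  z <- 1 / fit$slope
  d_tref <- 10^fit$intercept
  z_ci <- propagate_delta("z_from_inv_z", z, fit$t_crit * fit$se_slope)
  d_ci <- propagate_delta("d_from_log_d", d_tref,
                          fit$t_crit * fit$se_intercept)
  structure(
    list(t_ref = t_ref, d_tref = d_tref, d_tref_ci95_half = d_ci,
         z = z, z_ci95_half = z_ci, alpha = alpha, table = table, fit = fit),
    class = "bigelow_fit")
}

#' @export
print.bigelow_fit <- function(x, ...) {
  cat("Bigelow secondary model (T_ref = ", x$t_ref, " degC, ",
      x$fit$n, " temperatures)\n", sep = "")
  cat(sprintf("  D_Tref: %.1f +/- %.1f min\n", x$d_tref, x$d_tref_ci95_half))
  cat(sprintf("  z:      %.1f +/- %.1f degC\n", x$z, x$z_ci95_half))
  invisible(x)
}

#' @export
coef.bigelow_fit <- function(object, ...) {
  c(d_tref = object$d_tref, z = object$z)
}

#' @export
confint.bigelow_fit <- function(object, parm = c("d_tref", "z"), level, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  est <- c(d_tref = object$d_tref, z = object$z)[parm]
  hw <- c(d_tref = object$d_tref_ci95_half, z = object$z_ci95_half)[parm]
  out <- cbind(lower = est - hw, upper = est + hw)
  rownames(out) <- parm
  out
}

#' @export
residuals.bigelow_fit <- function(object, ...) object$fit$residuals

#' Predicted D-values with optional confidence/prediction bands
#'
#' Evaluates the fitted secondary model at new temperatures. Band
#' half-widths are computed on the log10 D scale (where the model is linear)
#' and the interval endpoints are back-transformed, so returned intervals are
#' asymmetric on the D scale.
#'
#' @param object a [fit_secondary()] result.
#' @param temperature temperatures (degC) at which to predict.
#' @param interval `"none"`, `"confidence"` (mean response) or
#'   `"prediction"` (new observation).
#' @param ... unused.
#' @return A data frame with `temperature`, `d_value`, and for intervals
#'   `lower`/`upper` (min).
#' @export
predict.bigelow_fit <- function(object, temperature = object$table$temperature,
                                interval = c("none", "confidence", "prediction"),
                                ...) {
  interval <- match.arg(interval)
  x0 <- object$t_ref - as.numeric(temperature)
  log_d <- predict(object$fit, x0)
  out <- data.frame(temperature = as.numeric(temperature),
                    d_value = 10^log_d)
  if (interval != "none") {
    hw <- switch(interval,
                 confidence = confidence_band(object$fit, x0),
                 prediction = prediction_band(object$fit, x0))
    out$lower <- 10^(log_d - hw)
    out$upper <- 10^(log_d + hw)
  }
  out
}

#' @export
summary.bigelow_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.bigelow_fit")
}

#' @export
print.summary.bigelow_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nRegression of log10(D) on T_ref - T:\n")
  print(f$fit)
  cat("\nD-value table:\n")
  print(as.data.frame(f$table), row.names = FALSE)
  invisible(x)
}

#' Plot the secondary regression with confidence and prediction bands
#'
#' Base-graphics plot of log10 D against `T_ref - T`: observed points, the
#' regression line, and 95% confidence (dashed) and prediction (dotted)
#' bands.
#'
#' @param x a [fit_secondary()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bigelow_fit <- function(x, ...) {
  xx <- x$fit$x
  grid <- seq(min(xx) - 2, max(xx) + 2, length.out = 101)
  yhat <- predict(x$fit, grid)
  cb <- confidence_band(x$fit, grid)
  pb <- prediction_band(x$fit, grid)
  graphics::plot(xx, x$fit$y, xlab = "T_ref - T (degC)",
                 ylab = "log10 D (min)",
                 ylim = range(yhat - pb, yhat + pb, x$fit$y), ...)
  graphics::lines(grid, yhat)
  graphics::lines(grid, yhat - cb, lty = 2, col = 2)
  graphics::lines(grid, yhat + cb, lty = 2, col = 2)
  graphics::lines(grid, yhat - pb, lty = 3)
  graphics::lines(grid, yhat + pb, lty = 3)
  invisible(x)
}
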