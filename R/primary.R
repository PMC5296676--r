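#' Isothermal survivor curve
#'
#' Bundles one constant-temperature survivor/degradation curve: observation
#' times in minutes and log10 concentrations. Raw concentrations may be
#' supplied instead of log10 values; they must be strictly positive and are
#' log-transformed on construction.
#'
#' @param temperature temperature of the isothermal experiment, in degrees C.
#' @param times observation times in minutes; non-negative, at least 3, at
#'   least 2 distinct.
#' @param log_conc log10 concentrations, same length as `times`. Exactly one
#'   of `log_conc` and `conc` must be given.
#' @param conc raw concentrations (> 0); converted with `log10()`.
#' @param label optional free-text label.
#' @return An object of class `"isothermal_dataset"`.
#' @examples
#' d <- isothermal_dataset(80, times = seq(0, 50, 10),
#'                         log_conc = 2 - seq(0, 50, 10) / 100)
#' fit_primary(d)
#' @export
isothermal_dataset <- function(temperature, times, log_conc = NULL,
                               conc = NULL, label = "") {
  if (!is.numeric(temperature) || length(temperature) != 1L || is.na(temperature))
    stop("'temperature' must be a single number", call. = FALSE)
  times <- as.numeric(times)
  if (is.null(log_conc) == is.null(conc))
    stop("supply exactly one of 'log_conc' or 'conc'", call. = FALSE)
  if (!is.null(conc)) {
    conc <- as.numeric(conc)
    if (any(is.na(conc)) || any(conc <= 0))
      stop("raw concentrations must be positive to take log10", call. = FALSE)
    log_conc <- log10(conc)
  }
  log_conc <- as.numeric(log_conc)
  if (length(times) != length(log_conc))
    stop("'times' and concentrations must have equal length", call. = FALSE)
  if (length(times) < 3L)
    stop("at least 3 observations are required", call. = FALSE)
  if (anyNA(times) || anyNA(log_conc))
    stop("missing values are not allowed", call. = FALSE)
  if (any(times < 0))
    stop("'times' must be non-negative", call. = FALSE)
  if (length(unique(times)) < 2L)
    stop("at least 2 distinct time points are required", call. = FALSE)
  structure(
    list(temperature = temperature, times = times, log_conc = log_conc,
         label = as.character(label)[1L]),
    class = "isothermal_dataset")
}

#' @export
print.isothermal_dataset <- function(x, ...) {
  cat("Isothermal survivor curve at ", x$temperature, " degC (",
      length(x$times), " points, t = ", min(x$times), "-", max(x$times),
      " min)", if (nzchar(x$label)) paste0(" [", x$label, "]"), "\n", sep = "")
  invisible(x)
}

#' Fit the log-linear primary inactivation model
#'
#' Regresses log10 concentration on time for one isothermal curve,
#' `log10 C = log10 C0 - t / D_T`, and returns the decimal reduction time
#' `D_T = -1/slope` with a delta-method 95% confidence half-width:
#' the t-interval half-width of the slope, `t_crit * se_slope`, is the
#' half-width of `1/D_T` and transforms to the D scale as
#' `D_T^2 * t_crit * se_slope`.
#'
#' @param dataset an [isothermal_dataset()].
#' @param alpha two-sided significance level for the interval (default 0.05).
#' @return An object of class `"dt_fit"`: list with `temperature`, `d_value`
#'   (min), `ci95_half` (min), `log_c0` (fitted intercept), and `fit`, the
#'   underlying [ols_fit()].
#' @section Errors: a non-negative fitted slope means no measurable
#'   inactivation and `D_T` is undefined; this is an error, not an `NA`.
#' @export
fit_primary <- function(dataset, alpha = 0.05) {
  if (!inherits(dataset, "isothermal_dataset"))
    stop("'dataset' must be an isothermal_dataset", call. = FALSE)
  fit <- ols_fit(dataset$times, dataset$log_conc, alpha = alpha)
  if (fit$slope >= 0)
    stop("no inactivation: slope of log10 C vs time is non-negative (",
         format(fit$slope, digits = 4), "); D_T is undefined", call. = FALSE)
  d_value <- -1 / fit$slope
  ci95_half <- propagate_delta("d_from_inv_d", d_value,
                               fit$t_crit * fit$se_slope)
  structure(
    list(temperature = dataset$temperature, d_value = d_value,
         ci95_half = ci95_half, log_c0 = fit$intercept,
         label = dataset$label, fit = fit),
    class = "dt_fit")
}

#' @export
print.dt_fit <- function(x, ...) {
  cat(sprintf("D-value at %g degC: %.4g min (95%% CI half-width %.4g min)\n",
              x$temperature, x$d_value, x$ci95_half))
  invisible(x)
}

#' @export
coef.dt_fit <- function(object, ...) {
  c(d_value = object$d_value, log_c0 = object$log_c0)
}

#' @export
residuals.dt_fit <- function(object, ...) object$fit$residuals
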