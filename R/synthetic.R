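#' Specification of a synthetic isothermal survivor curve
#'
#' Describes the data-generating process for one isothermal experiment:
#' the true log-linear decay `log10 C = log_c0 - t / d_value` plus additive
#' normal noise on the log10 concentration scale (the scale on which the
#' primary model is linear and fitted).
#'
#' The default time grid spans about two log reductions in seven points —
#' a typical bench design for an isothermal inactivation run.
#'
#' @param temperature temperature in degC.
#' @param d_value true decimal reduction time in minutes, `> 0`.
#' @param log_c0 true log10 initial concentration (default 2).
#' @param times sampling times in minutes (default 7 points from 0 to
#'   `2 * d_value`).
#' @param noise_sd SD of the additive normal noise on log10 concentration,
#'   `>= 0`.
#' @param n_replicates independent replicates per time point (default 1).
#' @return list of class `"curve_spec"`.
#' @export
curve_spec <- function(temperature, d_value, log_c0 = 2,
                       times = seq(0, 2 * d_value, length.out = 7),
                       noise_sd = 0.02, n_replicates = 1) {
  stopifnot(is.numeric(d_value), length(d_value) == 1L, d_value > 0,
            is.numeric(noise_sd), length(noise_sd) == 1L, noise_sd >= 0,
            is.numeric(n_replicates), n_replicates >= 1)
  times <- as.numeric(times)
  if (length(times) < 3L || any(times < 0) || length(unique(times)) < 2L)
    stop("'times' must be >= 3 non-negative values with >= 2 distinct",
         call. = FALSE)
  structure(
    list(temperature = temperature, d_value = d_value, log_c0 = log_c0,
         times = times, noise_sd = noise_sd,
         n_replicates = as.integer(n_replicates)),
    class = "curve_spec")
}

#' Generate a synthetic isothermal survivor curve
#'
#' Draws `log10 C = log_c0 - t / d_value + e`, with `e` independent
#' Normal(0, `noise_sd`) per observation, at the spec's time grid repeated
#' `n_replicates` times. Uses the current RNG stream unless `seed` is given.
#'
#' @param spec a [curve_spec()].
#' @param seed optional integer seed.
#' @return an [isothermal_dataset()].
#' @examples
#' spec <- curve_spec(80, d_value = 896.3, noise_sd = 0)
#' fit_primary(generate_isothermal(spec))$d_value  # exactly 896.3
#' @export
generate_isothermal <- function(spec, seed = NULL) {
  if (!inherits(spec, "curve_spec"))
    stop("'spec' must be a curve_spec", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  times <- rep(spec$times, spec$n_replicates)
  eps <- if (spec$noise_sd > 0) stats::rnorm(length(times), 0, spec$noise_sd)
         else numeric(length(times))
  isothermal_dataset(spec$temperature, times,
                     log_conc = spec$log_c0 - times / spec$d_value + eps,
                     label = "synthetic")
}

#' Sampling distribution of the fitted D-value under repeated synthetic
#' experiments
#'
#' Repeats generate-then-fit `n_datasets` times and returns all D-value
#' estimates with shape diagnostics (skewness and excess kurtosis, plus
#' histogram bin counts), to check that the estimator's sampling
#' distribution is approximately normal at the given noise level. Replicates
#' whose fitted slope is non-negative (no apparent inactivation) are
#' rejected and redrawn, with a count.
#'
#' @param spec a [curve_spec()] with `noise_sd > 0` for a non-degenerate
#'   distribution.
#' @param n_datasets number of synthetic datasets, `>= 100`.
#' @param seed optional integer seed.
#' @param breaks passed to [graphics::hist()] (computation only) for the
#'   returned bin counts.
#' @return list of class `"dt_sampling"` with `d_values`, `mean`, `sd`,
#'   `skewness`, `excess_kurtosis` (both `NA` when the estimates are
#'   constant), `histogram` (a `hist`-style list of breaks and counts) and
#'   `n_rejected`.
#' @export
dt_sampling_distribution <- function(spec, n_datasets = 1000, seed = NULL,
                                     breaks = "Sturges") {
  if (!inherits(spec, "curve_spec"))
    stop("'spec' must be a curve_spec", call. = FALSE)
  n_datasets <- as.integer(n_datasets)
  if (n_datasets < 100L)
    stop("'n_datasets' must be at least 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  d <- numeric(n_datasets)
  n_rejected <- 0L
  for (i in seq_len(n_datasets)) {
    repeat {
      est <- tryCatch(fit_primary(generate_isothermal(spec))$d_value,
                      error = function(e) NA_real_)
      if (!is.na(est)) break
      n_rejected <- n_rejected + 1L
      if (n_rejected > 10L * n_datasets)
        stop("too many rejected replicates; noise overwhelms the signal",
             call. = FALSE)
    }
    d[i] <- est
  }
  s <- stats::sd(d)
  m2 <- mean((d - mean(d))^2)   # population central moment, b1 convention
  if (m2 > 0) {
    zc <- (d - mean(d)) / sqrt(m2)
    skew <- mean(zc^3)
    exkurt <- mean(zc^4) - 3
  } else {
    skew <- exkurt <- NA_real_
  }
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  structure(
    list(d_values = d, mean = mean(d), sd = s, skewness = skew,
         excess_kurtosis = exkurt,
         histogram = list(breaks = h$breaks, counts = h$counts),
         n_rejected = n_rejected),
    class = "dt_sampling")
}

#' @export
print.dt_sampling <- function(x, ...) {
  cat("Sampling distribution of the fitted D-value (",
      length(x$d_values), " synthetic datasets)\n", sep = "")
  cat(sprintf("  mean %.4g, sd %.4g, skewness %.3f, excess kurtosis %.3f\n",
              x$mean, x$sd, x$skewness, x$excess_kurtosis))
  if (x$n_rejected > 0)
    cat("  ", x$n_rejected, " replicate(s) rejected and redrawn\n", sep = "")
  invisible(x)
}
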