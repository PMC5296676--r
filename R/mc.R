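#' Monte Carlo configuration
#'
#' Settings for the nested (two-stage) Monte Carlo propagation. Defaults
#' mirror the reference workflow: 500 outer D-value sets, 500 inner draws
#' per fitted parameter, reference temperature 120 degC, a 95% CI treated as
#' 2 sigma in both directions (input conversion and pooled summary), and
#' discretized-normal bins truncated at 4 sigma.
#'
#' @param n_outer number of outer D-value sets (default 500).
#' @param n_inner number of inner draws per outer fit (default 500).
#' @param seed root integer seed; named substreams are derived from it so
#'   each temperature, stage and sensitivity size is independently
#'   reproducible.
#' @param t_ref reference temperature in degC (default 120).
#' @param ci_to_sigma_factor divisor converting an input 95% CI half-width
#'   to the sampling sigma (default 2; use 1.96 for the exact normal
#'   quantile, or `qt(0.975, df)` for a t convention).
#' @param summary_ci_factor multiplier converting the pooled SD to the
#'   reported 95% CI half-width (default 2, mirroring the input convention).
#' @param truncation_half_width_sigma extent of the discretized-normal bins
#'   in sigma units (default 4); tail mass is folded into the outermost bins.
#' @param alpha significance level for the per-fit coefficient intervals
#'   (default 0.05).
#' @param stage2_sampling `"discretized"` (default) applies the same
#'   0.5-sigma discretization to the fitted parameters; `"normal"` draws
#'   from the continuous normal instead.
#' @param summary_method `"sd"` (default) reports
#'   `summary_ci_factor * sd`; `"percentile"` reports half the 2.5%-97.5%
#'   inter-quantile range.
#' @param reject_policy what to do when an outer D-value set yields a
#'   non-positive secondary slope: `"redraw"` (default, with a logged count)
#'   or `"error"`.
#' @param max_reject_rate abort threshold for the redraw policy
#'   (default 0.2).
#' @return a list of class `"mc_config"`.
#' @export
mc_config <- function(n_outer = 500, n_inner = 500, seed = 1, t_ref = 120,
                      ci_to_sigma_factor = 2, summary_ci_factor = 2,
                      truncation_half_width_sigma = 4, alpha = 0.05,
                      stage2_sampling = c("discretized", "normal"),
                      summary_method = c("sd", "percentile"),
                      reject_policy = c("redraw", "error"),
                      max_reject_rate = 0.2) {
  n_outer <- as.integer(n_outer)
  n_inner <- as.integer(n_inner)
  stopifnot(n_outer >= 1L, n_inner >= 1L,
            ci_to_sigma_factor > 0, summary_ci_factor > 0,
            truncation_half_width_sigma > 0,
            alpha > 0, alpha < 1, max_reject_rate > 0)
  structure(
    list(n_outer = n_outer, n_inner = n_inner, seed = as.integer(seed),
         t_ref = t_ref, ci_to_sigma_factor = ci_to_sigma_factor,
         summary_ci_factor = summary_ci_factor,
         truncation_half_width_sigma = truncation_half_width_sigma,
         alpha = alpha, stage2_sampling = match.arg(stage2_sampling),
         summary_method = match.arg(summary_method),
         reject_policy = match.arg(reject_policy),
         max_reject_rate = max_reject_rate),
    class = "mc_config")
}

#' Summarize a pooled Monte Carlo sample
#'
#' Sample mean, sample SD (n - 1 denominator) and the reported 95% CI
#' half-width under the configured convention (`summary_ci_factor * sd`, or
#' the percentile half-range).
#'
#' @param values numeric vector, length `>= 2`.
#' @param config an [mc_config()].
#' @return list with `mean`, `sd`, `ci95_half`, `n`.
#' @export
summarize_pooled <- function(values, config = mc_config()) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("at least 2 values are required", call. = FALSE)
  m <- mean(values)
  s <- stats::sd(values)
  hw <- switch(config$summary_method,
    sd = config$summary_ci_factor * s,
    percentile = diff(stats::quantile(values, c(0.025, 0.975),
                                      names = FALSE)) / 2)
  list(mean = m, sd = s, ci95_half = hw, n = length(values))
}

# one outer draw matrix: n_outer joint D-value sets, one column per
# temperature, independent across temperatures, each from its own
# discretized normal and named RNG substream
draw_outer_sets <- function(table, config, stream = "outer") {
  sig <- table$ci95_half / config$ci_to_sigma_factor
  cols <- lapply(seq_len(nrow(table)), function(j) {
    set.seed(derive_seed(config$seed, stream, table$temperature[j]))
    d <- discretize_normal(table$d_value[j], sig[j],
                           config$truncation_half_width_sigma)
    sample_discretized(d, config$n_outer)
  })
  matrix(unlist(cols), nrow = config$n_outer)
}

#' Nested Monte Carlo propagation of D-value uncertainty to the secondary
#' model parameters
#'
#' Stage 1 draws `n_outer` joint sets of one D-value per temperature, each
#' from the discretized normal with mean equal to the tabulated D and sigma
#' equal to its 95% CI half-width divided by `ci_to_sigma_factor`, and fits
#' the Bigelow secondary model to every set, giving `n_outer` pairs of
#' (estimate, 95% CI half-width) for `D_Tref` and `z`. Stage 2 treats each
#' outer estimate as the mean of a normal with sigma equal to its own CI
#' half-width over `ci_to_sigma_factor`, and draws `n_inner` values from
#' each (discretized the same way by default). The pooled
#' `n_outer * n_inner` values per parameter define the reported mean, SD
#' and 95% CI half-width.
#'
#' `D_Tref` and `z` are sampled independently in stage 2; the regression
#' correlation between them is deliberately not propagated.
#'
#' Outer sets whose secondary regression has a non-positive slope (possible
#' when input CIs are wide) are rejected and redrawn under the default
#' policy, with the count reported in the result; the run aborts if the
#' rejection rate exceeds `max_reject_rate`.
#'
#' @param table a [dt_table()] with non-degenerate `ci95_half` values (zeros
#'   are allowed and degenerate to the deterministic fit).
#' @param config an [mc_config()].
#' @return An object of class `"bigelow_mc"`: list with components
#'   `d_tref` and `z` (each a list with `mean`, `sd`, `ci95_half`, `pooled`
#'   — the full pooled sample — and `per_outer`, a data frame of the outer
#'   estimates and their CI half-widths), `deterministic` (the
#'   [fit_secondary()] of the input table), `n_rejected`, and `config`.
#' @examples
#' tab <- carnitine_dt("original")
#' mc <- run_two_stage_mc(tab, mc_config(n_outer = 50, n_inner = 50, seed = 7))
#' mc
#' @export
run_two_stage_mc <- function(table, config = mc_config()) {
  if (!inherits(table, "dt_table"))
    stop("'table' must be a dt_table", call. = FALSE)
  if (!inherits(config, "mc_config"))
    stop("'config' must be an mc_config", call. = FALSE)

  deterministic <- fit_secondary(table, t_ref = config$t_ref,
                                 alpha = config$alpha)

  # Stage 1: outer joint D-value sets and per-set secondary fits
  D <- draw_outer_sets(table, config)
  fit_one <- function(d_row) {
    tryCatch(fit_secondary(dt_table(table$temperature, d_row),
                           t_ref = config$t_ref, alpha = config$alpha),
             error = function(e) NULL)
  }
  fits <- lapply(seq_len(nrow(D)), function(i) fit_one(D[i, ]))
  n_rejected <- 0L
  bad <- which(vapply(fits, is.null, logical(1)))
  if (length(bad) && config$reject_policy == "error")
    stop(length(bad), " outer D-value set(s) gave a non-positive secondary ",
         "slope", call. = FALSE)
  redraw_round <- 0L
  while (length(bad)) {
    n_rejected <- n_rejected + length(bad)
    if (n_rejected / (config$n_outer + n_rejected) > config$max_reject_rate)
      stop("rejection rate of degenerate outer draws exceeds ",
           config$max_reject_rate, "; input CIs are too wide for the ",
           "redraw policy", call. = FALSE)
    redraw_round <- redraw_round + 1L
    sig <- table$ci95_half / config$ci_to_sigma_factor
    for (i in seq_along(bad)) {
      row <- vapply(seq_len(nrow(table)), function(j) {
        set.seed(derive_seed(config$seed, "redraw", redraw_round, i,
                             table$temperature[j]))
        dn <- discretize_normal(table$d_value[j], sig[j],
                                config$truncation_half_width_sigma)
        sample_discretized(dn, 1L)
      }, numeric(1))
      fits[[bad[i]]] <- fit_one(row)
    }
    bad <- which(vapply(fits, is.null, logical(1)))
  }

  per_outer <- function(est_field, ci_field) {
    data.frame(
      estimate = vapply(fits, `[[`, numeric(1), est_field),
      ci95_half = vapply(fits, `[[`, numeric(1), ci_field))
  }
  outer_d <- per_outer("d_tref", "d_tref_ci95_half")
  outer_z <- per_outer("z", "z_ci95_half")

  # Stage 2: inner draws around each outer estimate
  stage2 <- function(outer, label) {
    set.seed(derive_seed(config$seed, "inner", label))
    sig <- outer$ci95_half / config$ci_to_sigma_factor
    pooled <- vector("list", nrow(outer))
    for (i in seq_len(nrow(outer))) {
      pooled[[i]] <- if (config$stage2_sampling == "discretized") {
        dn <- discretize_normal(outer$estimate[i], sig[i],
                                config$truncation_half_width_sigma)
        sample_discretized(dn, config$n_inner)
      } else {
        stats::rnorm(config$n_inner, outer$estimate[i], sig[i])
      }
    }
    unlist(pooled, use.names = FALSE)
  }
  pooled_d <- stage2(outer_d, "d_tref")
  pooled_z <- stage2(outer_z, "z")

  res <- function(pooled, outer) {
    c(summarize_pooled(pooled, config),
      list(pooled = pooled, per_outer = outer))
  }
  structure(
    list(d_tref = res(pooled_d, outer_d), z = res(pooled_z, outer_z),
         deterministic = deterministic, n_rejected = n_rejected,
         config = config),
    class = "bigelow_mc")
}

#' @export
print.bigelow_mc <- function(x, ...) {
  cat("Nested Monte Carlo propagation (", x$config$n_outer, " x ",
      x$config$n_inner, " draws, T_ref = ", x$config$t_ref, " degC)\n",
      sep = "")
  cat(sprintf("  D_Tref: %.1f +/- %.1f min   (deterministic %.1f +/- %.1f)\n",
              x$d_tref$mean, x$d_tref$ci95_half,
              x$deterministic$d_tref, x$deterministic$d_tref_ci95_half))
  cat(sprintf("  z:      %.1f +/- %.1f degC  (deterministic %.1f +/- %.1f)\n",
              x$z$mean, x$z$ci95_half,
              x$deterministic$z, x$deterministic$z_ci95_half))
  if (x$n_rejected > 0)
    cat("  rejected and redrew ", x$n_rejected,
        " degenerate outer set(s)\n", sep = "")
  invisible(x)
}

#' @export
summary.bigelow_mc <- function(object, ...) {
  out <- data.frame(
    parameter = c("d_tref", "z"),
    mean = c(object$d_tref$mean, object$z$mean),
    sd = c(object$d_tref$sd, object$z$sd),
    ci95_half = c(object$d_tref$ci95_half, object$z$ci95_half),
    n_pooled = c(object$d_tref$n, object$z$n))
  out
}

#' Histogram of the pooled Monte Carlo sample
#' @param x a [run_two_stage_mc()] result.
#' @param parameter which pooled sample to plot.
#' @param ... passed to [graphics::hist()].
#' @export
plot.bigelow_mc <- function(x, parameter = c("d_tref", "z"), ...) {
  parameter <- match.arg(parameter)
  graphics::hist(x[[parameter]]$pooled, breaks = 60, freq = FALSE,
                 main = paste("Pooled", parameter, "sample"),
                 xlab = parameter, ...)
  invisible(x)
}

#' Validate the discretized-normal sampler against the input table
#'
#' Draws `n` values from each temperature's discretized normal and reports
#' the recovered mean and 95% CI half-width (`summary_ci_factor * sd`) next
#' to the inputs. With moderate `n` the recovered values should sit within
#' sampling error of the tabulated ones.
#'
#' @param table a [dt_table()].
#' @param n draws per temperature (default 500).
#' @param config an [mc_config()].
#' @return data frame with one row per temperature: `temperature`,
#'   `d_value`, `ci95_half` (inputs), `recovered_mean`, `recovered_ci95_half`.
#' @export
validate_sampler <- function(table, n = 500, config = mc_config()) {
  if (!inherits(table, "dt_table"))
    stop("'table' must be a dt_table", call. = FALSE)
  sig <- table$ci95_half / config$ci_to_sigma_factor
  rec <- t(vapply(seq_len(nrow(table)), function(j) {
    set.seed(derive_seed(config$seed, "validate", table$temperature[j]))
    d <- discretize_normal(table$d_value[j], sig[j],
                           config$truncation_half_width_sigma)
    v <- sample_discretized(d, n)
    c(mean(v), if (n > 1) config$summary_ci_factor * stats::sd(v) else 0)
  }, numeric(2)))
  data.frame(temperature = table$temperature, d_value = table$d_value,
             ci95_half = table$ci95_half,
             recovered_mean = rec[, 1], recovered_ci95_half = rec[, 2])
}

#' Sensitivity of the pooled summaries to the Monte Carlo sample sizes
#'
#' Re-runs the nested propagation at each requested size with an
#' independent seed substream and tabulates the pooled mean, SD and CI
#' half-width per parameter, to check how many draws are needed before the
#' reported intervals stabilize.
#'
#' @param table a [dt_table()].
#' @param sizes integer vector of sizes, each used as
#'   `n_outer = n_inner = size`, or a 2-column matrix of
#'   `(n_outer, n_inner)` pairs.
#' @param config an [mc_config()]; its `n_outer`/`n_inner` are overridden
#'   per size.
#' @return data frame of class `"sensitivity_result"` with columns
#'   `n_outer`, `n_inner`, `parameter`, `mean`, `sd`, `ci95_half`,
#'   `n_rejected`.
#' @export
sensitivity_analysis <- function(table, sizes = c(25, 100, 250, 500),
                                 config = mc_config()) {
  if (is.matrix(sizes)) {
    stopifnot(ncol(sizes) == 2L, nrow(sizes) >= 1L)
    pairs <- sizes
  } else {
    sizes <- as.integer(sizes)
    stopifnot(length(sizes) >= 1L, all(sizes >= 1L))
    pairs <- cbind(sizes, sizes)
  }
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    cfg <- config
    cfg$n_outer <- as.integer(pairs[i, 1L])
    cfg$n_inner <- as.integer(pairs[i, 2L])
    cfg$seed <- derive_seed(config$seed, "size", cfg$n_outer, cfg$n_inner)
    mc <- run_two_stage_mc(table, cfg)
    s <- summary(mc)
    rows[[i]] <- data.frame(n_outer = cfg$n_outer, n_inner = cfg$n_inner,
                            s, n_rejected = mc$n_rejected)
  }
  structure(do.call(rbind, rows),
            class = c("sensitivity_result", "data.frame"))
}
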