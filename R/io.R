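#' Read isothermal survivor curves from CSV
#'
#' Expects columns `temperature_C`, `time_min` and either `log10_conc` or
#' `conc` (raw concentrations, log-transformed on read). One file may hold
#' several temperatures; rows are grouped by `temperature_C`.
#'
#' @param path CSV file path.
#' @return named list of [isothermal_dataset()] objects, one per
#'   temperature, names like `"80"`.
#' @export
read_survivor_curves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("temperature_C", "time_min") %in% names(df)))
    stop("'", path, "': need columns temperature_C, time_min and ",
         "log10_conc or conc", call. = FALSE)
  has_log <- "log10_conc" %in% names(df)
  if (!has_log && !("conc" %in% names(df)))
    stop("'", path, "': need a log10_conc or conc column", call. = FALSE)
  for (col in c("temperature_C", "time_min", if (has_log) "log10_conc" else "conc")) {
    if (!is.numeric(df[[col]]))
      stop("'", path, "': column ", col, " is not numeric", call. = FALSE)
  }
  out <- lapply(split(df, df$temperature_C), function(g) {
    if (has_log)
      isothermal_dataset(g$temperature_C[1L], g$time_min,
                         log_conc = g$log10_conc)
    else
      isothermal_dataset(g$temperature_C[1L], g$time_min, conc = g$conc)
  })
  out[order(as.numeric(names(out)))]
}

#' Read a D-value table from CSV
#'
#' Expects header `temperature_C,D_min,CI95_half_min`. Validation failures
#' report the offending row.
#'
#' @param path CSV file path.
#' @return a [dt_table()].
#' @export
read_dt_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("temperature_C", "D_min", "CI95_half_min")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("'", path, "': missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L)
    stop("'", path, "': no data rows", call. = FALSE)
  for (col in need) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
      stop("'", path, "': non-numeric value in column ", col,
           " at data row ", if (length(bad)) bad else "?", call. = FALSE)
    }
  }
  if (any(df$D_min <= 0))
    stop("'", path, "': non-positive D at data row ",
         which(df$D_min <= 0)[1L], call. = FALSE)
  if (anyDuplicated(df$temperature_C))
    stop("'", path, "': duplicate temperature at data row ",
         anyDuplicated(df$temperature_C), call. = FALSE)
  dt_table(df$temperature_C, df$D_min, df$CI95_half_min)
}

#' Write a D-value table to CSV
#' @param table a [dt_table()].
#' @param path output file path.
#' @export
write_dt_table <- function(table, path) {
  stopifnot(inherits(table, "dt_table"))
  utils::write.csv(
    data.frame(temperature_C = table$temperature, D_min = table$d_value,
               CI95_half_min = table$ci95_half),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The l-carnitine thermal inactivation D-value table
#'
#' Packaged fixture: mean D-values at eight temperatures (80-130 degC) of
#' l-carnitine thermal degradation with their 95% CI half-widths, in two
#' variants — the original (narrow) experimental CIs, and a version with
#' intentionally expanded CIs used to study uncertainty propagation when
#' primary-model errors are large.
#'
#' @param errors `"original"` (narrow CIs) or `"expanded"`.
#' @return a [dt_table()] with 8 rows.
#' @examples
#' fit_secondary(carnitine_dt("original"), t_ref = 120)
#' @export
carnitine_dt <- function(errors = c("original", "expanded")) {
  errors <- match.arg(errors)
  path <- system.file("extdata", paste0("carnitine_dt_", errors, ".csv"),
                      package = "thermoprop", mustWork = TRUE)
  read_dt_table(path)
}

#' Write a result object to JSON or CSV
#'
#' Serializes deterministic fits ([fit_secondary()]), Monte Carlo runs
#' ([run_two_stage_mc()]) and sensitivity tables ([sensitivity_analysis()])
#' with enough of the configuration (including the seed) to reproduce them.
#'
#' @param x a `bigelow_fit`, `bigelow_mc` or `sensitivity_result`.
#' @param path output file path.
#' @param format `"json"` or `"csv"`. CSV writes one row per
#'   (parameter, statistic).
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = c("json", "csv")) {
  format <- match.arg(format)
  payload <- result_payload(x)
  if (format == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    long <- payload_to_long(payload)
    utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

result_payload <- function(x) {
  if (inherits(x, "bigelow_fit")) {
    list(kind = "deterministic_fit", t_ref = x$t_ref, alpha = x$alpha,
         estimates = list(
           d_tref = list(value = x$d_tref, ci95_half = x$d_tref_ci95_half),
           z = list(value = x$z, ci95_half = x$z_ci95_half)))
  } else if (inherits(x, "bigelow_mc")) {
    cfg <- unclass(x$config)
    list(kind = "two_stage_mc", config = cfg,
         n_rejected = x$n_rejected,
         estimates = list(
           d_tref = list(mean = x$d_tref$mean, sd = x$d_tref$sd,
                         ci95_half = x$d_tref$ci95_half),
           z = list(mean = x$z$mean, sd = x$z$sd,
                    ci95_half = x$z$ci95_half)),
         deterministic = result_payload(x$deterministic))
  } else if (inherits(x, "sensitivity_result")) {
    list(kind = "sensitivity", rows = as.data.frame(x))
  } else {
    stop("don't know how to serialize a ", class(x)[1L], call. = FALSE)
  }
}

payload_to_long <- function(payload) {
  if (payload$kind == "sensitivity") return(payload$rows)
  est <- payload$estimates
  rows <- do.call(rbind, lapply(names(est), function(p) {
    st <- est[[p]]
    data.frame(parameter = p, statistic = names(st),
               value = unlist(st, use.names = FALSE))
  }))
  rows
}

#' Read back a JSON results file
#' @param path file written by [write_results()] with `format = "json"`.
#' @return the deserialized list.
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
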