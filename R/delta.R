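#' First-order (delta-method) transforms of interval half-widths
#'
#' The two-step kinetic workflow estimates transformed parameters by linear
#' regression — `1/D_T` (negative slope of the survivor curve), `1/z` (slope
#' of the secondary regression) and `log10(D_Tref)` (its intercept) — and
#' converts the interval half-width of the transformed parameter back to the
#' natural scale through \eqn{\delta(f(x)) = |f'(x)|\,\delta(x)}:
#'
#' * `d_from_inv_d`: \eqn{\delta(D_T) = D_T^2\,\delta(1/D_T)}
#' * `z_from_inv_z`: \eqn{\delta(z) = z^2\,\delta(1/z)}
#' * `d_from_log_d`: \eqn{\delta(D_{Tref}) = \ln(10)\,D_{Tref}\,\delta(\log_{10} D_{Tref})}
#'
#' @param kind one of `"d_from_inv_d"`, `"z_from_inv_z"`, `"d_from_log_d"`.
#' @param value the parameter value on the natural scale (must be positive).
#' @param delta_in interval half-width of the transformed parameter
#'   (non-negative).
#' @return the interval half-width on the natural scale.
#' @examples
#' propagate_delta("d_from_inv_d", 100, 1e-4)    # 1
#' propagate_delta("d_from_log_d", 10, 1 / log(10))  # 10
#' @export
propagate_delta <- function(kind = c("d_from_inv_d", "z_from_inv_z", "d_from_log_d"),
                            value, delta_in) {
  kind <- match.arg(kind)
  if (!is.numeric(value) || any(value <= 0))
    stop("'value' must be positive", call. = FALSE)
  if (!is.numeric(delta_in) || any(delta_in < 0))
    stop("'delta_in' must be non-negative", call. = FALSE)
  switch(kind,
    d_from_inv_d = value^2 * delta_in,
    z_from_inv_z = value^2 * delta_in,
    d_from_log_d = log(10) * value * delta_in)
}
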