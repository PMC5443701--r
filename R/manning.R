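#' Manning condensed-charge fraction
#'
#' Classical counterion-condensation prediction for an infinite line
#' charge: for a dimensionless line-charge (Manning) parameter
#' \eqn{\xi = l_B / \lambda} (with \eqn{\lambda} the axial spacing between
#' elementary charges), the fraction of charge left uncompensated is
#' \eqn{\min(1, 1/\xi)}. Below the condensation threshold (\eqn{\xi \le 1})
#' no charge is condensed.
#'
#' @param manning_parameter dimensionless \eqn{\xi > 0}; vectorized.
#' @return effective-charge fraction in (0, 1].
#' @export
#' @examples
#' manning_fraction(4.2)  # dsDNA: ~0.238
manning_fraction <- function(manning_parameter) {
  if (any(manning_parameter <= 0))
    stop("manning_parameter must be positive", call. = FALSE)
  pmin(1, 1 / manning_parameter)
}

#' Manning parameter of double-stranded DNA
#'
#' \eqn{\xi = l_{B,w} \times (2 \; \mathrm{charges} / \mathrm{rise})} for
#' B-form DNA with two phosphates per base pair. With a 0.34 nm rise in
#' water at 25 C this gives 4.2.
#'
#' @param cond [solution_conditions()] (supplies the solvent Bjerrum
#'   length); defaults to water at 25 C.
#' @param rise_per_bp axial rise per base pair in nm (default 0.34).
#' @return dimensionless Manning parameter.
#' @export
dsdna_manning_parameter <- function(cond = solution_conditions(7, 0.1),
                                    rise_per_bp = 0.34) {
  stopifnot(inherits(cond, "solution_conditions"))
  if (rise_per_bp <= 0) stop("rise_per_bp must be positive", call. = FALSE)
  cond$lB * 2 / rise_per_bp
}
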