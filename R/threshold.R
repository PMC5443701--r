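#' Threshold potential for the onset of charge regulation
#'
#' Magnitude of the local potential at which the ionized fraction of a
#' group of given pKa drops to a chosen threshold fraction
#' \eqn{\eta_t}:
#' \deqn{|\tilde\psi_t| = |2.303(\mathrm{pH} - \mathrm{p}K_a) +
#'   \ln(1/\eta_t - 1)| - \phi_s,} floored at zero. If the Born penalty
#' \eqn{\phi_s} alone exceeds the chemistry term, the group regulates at
#' any potential and the threshold is degenerate (returned as 0 with
#' attribute `degenerate = TRUE`).
#'
#' @param pH bulk pH.
#' @param pKa group pKa.
#' @param eta_t threshold ionized fraction, in (0, 1) (e.g. 0.95 for the
#'   onset of a 5 percent departure from ideal ionization).
#' @param phi_s dimensionless Born penalty (default 0).
#' @return dimensionless potential magnitude (kBT/e units).
#' @export
threshold_potential <- function(pH, pKa, eta_t, phi_s = 0) {
  if (any(eta_t <= 0 | eta_t >= 1))
    stop("eta_t must lie in (0, 1)", call. = FALSE)
  if (any(phi_s < 0)) stop("phi_s must be non-negative", call. = FALSE)
  raw <- abs(log(10) * (pH - pKa) + log(1 / eta_t - 1)) - phi_s
  out <- pmax(raw, 0)
  attr(out, "degenerate") <- raw < 0
  out
}

#' Threshold charge for the onset of charge regulation in a sphere
#'
#' Solves the mean-interior-potential criterion
#' \deqn{\frac{|Q_t|}{R}\left\{\frac{l_{B,p}}{5} +
#'   \frac{l_{B,w}}{1+\kappa R}\right\} = |\tilde\psi_t|}
#' at equality for the threshold charge \eqn{|Q_t|} of a uniformly charged
#' dielectric sphere, and reports the dimensionless regulation criterion
#' \eqn{|Q_t| l_{B,p} / R}. When `psi_s_assumed` is supplied (the
#' surface-potential contribution in kBT, a reasonable high-salt estimate
#' being 2), the criterion is obtained by attributing that much of
#' \eqn{\tilde\psi_t} to the surface term, giving the R-independent rule of
#' thumb \eqn{|Q_t| l_{B,p}/R = 5(|\tilde\psi_t| - |\tilde\psi_s|)}
#' (about 10 for pH 7, pKa 4, \eqn{\eta_t} 0.95, \eqn{\phi_s} 0).
#'
#' @param radius sphere radius R in nm.
#' @param interior_dielectric interior dielectric constant.
#' @param cond [solution_conditions()].
#' @param psi_t threshold potential magnitude from
#'   [threshold_potential()].
#' @param psi_s_assumed optional assumed surface-potential contribution in
#'   kBT; if `NULL` (default) the full criterion is solved with the actual
#'   R, dielectric and screening.
#' @return A `threshold_result` list: `psi_t`, `Q_t` (elementary charges,
#'   magnitude), `dimensionless_criterion` = |Qt| lB,p / R, and
#'   `degenerate` flag.
#' @export
threshold_charge <- function(radius, interior_dielectric, cond, psi_t,
                             psi_s_assumed = NULL) {
  stopifnot(inherits(cond, "solution_conditions"))
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  degenerate <- isTRUE(any(attr(psi_t, "degenerate"))) || psi_t <= 0
  psi_t <- as.numeric(psi_t)
  lBp <- bjerrum_length(interior_dielectric, cond$temperature)
  lBw <- cond$lB
  kR <- cond$kappa * radius
  if (degenerate || psi_t <= 0) {
    res <- list(psi_t = max(psi_t, 0), Q_t = 0,
                dimensionless_criterion = 0, degenerate = TRUE)
    class(res) <- "threshold_result"
    return(res)
  }
  if (is.null(psi_s_assumed)) {
    Qt <- psi_t / (lBp / (5 * radius) + lBw / (radius * (1 + kR)))
    crit <- Qt * lBp / radius
  } else {
    crit <- 5 * max(psi_t - psi_s_assumed, 0)
    Qt <- crit * radius / lBp
  }
  res <- list(psi_t = psi_t, Q_t = Qt, dimensionless_criterion = crit,
              degenerate = FALSE)
  class(res) <- "threshold_result"
  res
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("Regulation threshold: |psi_t| = %.3f kBT/e, |Q_t| = %.3f e, |Q_t| lB,p/R = %.3f%s\n",
              x$psi_t, x$Q_t, x$dimensionless_criterion,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Debye-Hueckel surface potential of a charged sphere
#'
#' Linear-regime surface potential of a sphere of charge Q (in e) and
#' radius R in a screening electrolyte:
#' \eqn{\tilde\psi_s = Q l_{B,w} / (R (1 + \kappa R))}, signed with Q.
#'
#' @param charge total charge in elementary charges (signed).
#' @param radius sphere radius in nm.
#' @param cond [solution_conditions()].
#' @return dimensionless surface potential.
#' @export
dh_sphere_surface_potential <- function(charge, radius, cond) {
  stopifnot(inherits(cond, "solution_conditions"))
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  charge * cond$lB / (radius * (1 + cond$kappa * radius))
}

#' Volume-averaged interior potential of a uniformly charged sphere
#'
#' The parabolic interior profile of a uniformly charged dielectric sphere
#' (excess over the surface value) averages to
#' \eqn{\langle\tilde\psi\rangle_V = Q l_{B,p} / (5R)} where
#' \eqn{l_{B,p}} is the Bjerrum length evaluated with the interior
#' dielectric constant.
#'
#' @param charge total enclosed charge in elementary charges (signed).
#' @param radius sphere radius in nm.
#' @param interior_dielectric interior dielectric constant.
#' @param temperature kelvin (default 298.15).
#' @return dimensionless mean interior potential (excess over surface).
#' @export
mean_interior_potential <- function(charge, radius, interior_dielectric,
                                    temperature = 298.15) {
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  charge * bjerrum_length(interior_dielectric, temperature) / (5 * radius)
}
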