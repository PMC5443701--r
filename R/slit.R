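## 1-D planar nonlinear PB solve across an empty slit, and the mean
## slit potential over a virtual object surface.

#' Potential profile across an empty charged slit
#'
#' Solves the 1-D nonlinear Poisson-Boltzmann equation between two
#' like-charged parallel walls (constant surface charge `sigma` on each)
#' and returns the dimensionless potential on a fine node grid. Far from
#' the walls (and for moderate wall potentials) the profile approaches the
#' single-wall superposition
#' \eqn{\psi(z) = \psi_{wall}[e^{-\kappa z} + e^{-\kappa(2h - z)}]}.
#'
#' @param cond a [solution_conditions()].
#' @param height wall separation 2h in nm.
#' @param sigma wall surface charge in e/nm^2 (each wall, signed).
#' @param n number of nodes (default 1200).
#' @return list with nodes `z`, potential `psi`, and `psi_wall` (the
#'   surface value).
#' @export
slit_profile <- function(cond, height, sigma, n = 1200) {
  stopifnot(inherits(cond, "solution_conditions"))
  z <- seq(0, height, length.out = n)
  lB <- cond$lB; kap2 <- cond$kappa^2
  dz <- z[2] - z[1]
  vol <- rep(dz, n); vol[c(1, n)] <- dz / 2
  q <- rep(0, n); q[c(1, n)] <- sigma           # per unit area
  cf <- rep(1 / dz, n - 1)
  clamp <- function(p) pmin(pmax(p, -60), 60)
  psi <- rep(0, n)
  for (scale in c(0.5, 1)) {
    for (it in 1:60) {
      flux <- cf * (psi[-1] - psi[-n])
      div <- c(flux, 0) - c(0, flux)
      Fv <- div + 4 * pi * lB * scale * q - kap2 * sinh(clamp(psi)) * vol
      D <- kap2 * cosh(clamp(psi)) * vol
      M <- Matrix::bandSparse(n, n, k = -1:1,
        diagonals = list(-cf, c(cf, 0) + c(0, cf) + D, -cf))
      delta <- as.numeric(Matrix::solve(M, Fv))
      mx <- max(abs(delta))
      if (mx > 2) delta <- delta * (2 / mx)
      psi <- psi + delta
      if (max(abs(delta)) < 1e-10) break
    }
  }
  list(z = z, psi = psi, psi_wall = psi[1])
}

#' Mean slit potential over a virtual object surface
#'
#' Averages the empty-slit potential over a virtual contour tracing the
#' surface of an object centred at the slit mid-plane: the unperturbed
#' local potential \eqn{\langle\tilde\psi'(s)\rangle} entering the
#' interaction-charge definition. The average is area-weighted (exact for
#' the 1-D slit field: uniform in cos(theta) over a sphere; lateral strip
#' plus end caps for a cylinder).
#'
#' @param slit a [slit_geometry()].
#' @param cond a [solution_conditions()].
#' @param model a [sphere_model()] or [cylinder_model()] describing the
#'   virtual surface (only the geometry is used).
#' @param profile optional precomputed [slit_profile()] result.
#' @param orientation for cylinders: `"axial"` (axis along the slit
#'   normal, finite length) or `"parallel"` (infinite cylinder lying
#'   parallel to the walls; contour is its circular cross-section).
#' @return dimensionless mean potential over the virtual surface.
#' @export
slit_reference_potential <- function(slit, cond, model, profile = NULL,
                                     orientation = c("axial", "parallel")) {
  stopifnot(inherits(slit, "slit_geometry"))
  orientation <- match.arg(orientation)
  h <- slit$half_height
  half <- if (orientation == "parallel") model$radius else
    .object_half_extent(model)
  if (half >= h) stop("virtual surface intersects the walls", call. = FALSE)
  if (is.null(profile))
    profile <- slit_profile(cond, 2 * h, slit$wall_surface_charge)
  psi_at <- stats::approxfun(profile$z, profile$psi, rule = 2)
  nq <- 400
  if (inherits(model, "sphere_model")) {
    ## dA = 2 pi R^2 d(cos theta): uniform measure in u = cos(theta)
    u <- seq(-1 + 1 / nq, 1 - 1 / nq, length.out = nq)
    mean(psi_at(h + model$radius * u))
  } else if (orientation == "parallel") {
    ## circular cross-section contour, uniform in arc length
    th <- (seq_len(nq) - 0.5) / nq * 2 * pi
    mean(psi_at(h + model$radius * cos(th)))
  } else {
    R <- model$radius; L <- model$length
    zq <- seq(h - L / 2, h + L / 2, length.out = nq)
    lat <- mean(psi_at(zq)) * 2 * pi * R * L
    caps <- (psi_at(h - L / 2) + psi_at(h + L / 2)) * pi * R^2
    (lat + caps) / (2 * pi * R * L + 2 * pi * R^2)
  }
}
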