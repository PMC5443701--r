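## 1-D radial finite-volume solvers for the coupled interior-Poisson /
## exterior nonlinear Poisson-Boltzmann problem.
##
## Dimensionless formulation, psi = e psi_dim / kBT, lengths in nm:
##   div( (eps/eps_m) grad psi ) = kappa^2 sinh(psi)    (electrolyte)
##   div( (eps/eps_m) grad psi ) = -4 pi lB,w n(r,psi)  (charged layers)
## with n the signed number density of elementary charges, which for
## regulating layers depends on the local potential through the ionization
## fraction. Zero-flux conditions at r = 0 and at the outer truncation
## boundary (overall electroneutrality).

#' Solver control parameters
#'
#' @param tol convergence tolerance on the max Newton update of the
#'   dimensionless potential (default 1e-8).
#' @param max_iter maximum Newton iterations per ramp stage.
#' @param ramp charge ramp factors used as a nonlinear continuation path.
#' @param domain_factor outer truncation distance beyond the outermost
#'   charged surface, in Debye lengths (default 10).
#' @param mesh_scale multiplies every target mesh spacing; 0.5 halves all
#'   length scales (used by grid-convergence checks).
#' @param method `"newton"` (default) or `"picard"` (damped fixed point
#'   with a Debye-Hueckel preconditioner; slower, kept as an independent
#'   cross-check of the Newton path).
#' @return a list of class `pb_control`.
#' @export
pb_control <- function(tol = 1e-8, max_iter = 60, ramp = c(0.25, 0.5, 1),
                       domain_factor = 10, mesh_scale = 1,
                       method = c("newton", "picard")) {
  method <- match.arg(method)
  structure(list(tol = tol, max_iter = max_iter, ramp = ramp,
                 domain_factor = domain_factor, mesh_scale = mesh_scale,
                 method = method), class = "pb_control")
}

## ---------------------------------------------------------------------------
## generic multilayer radial solver
##
## layers: list of list(r_in, r_out, eps_rel, source) where source is
##   list(type = "ions") |
##   list(type = "fixed", density = e/nm^3) |
##   list(type = "regulated", groups = group_set, densities = counts/volume,
##        phi_s = per-group Born penalty, phi_0 = offset)
## geometry: "sphere" (full radial) or "cylinder" (per unit length, annular
##   domain starting at r_in of the first layer)
## surface: optional surface charge at the inner domain boundary r0:
##   list(type = "fixed", sigma = e/nm^2) |
##   list(type = "regulated", groups, sigmas = counts/area, phi_s, phi_0)
.pb_radial_solve <- function(layers, cond, geometry = c("sphere", "cylinder"),
                             surface = NULL, control = pb_control(),
                             axis = NULL) {
  geometry <- match.arg(geometry)
  lB <- cond$lB
  kap2 <- cond$kappa^2

  ## --- mesh ----------------------------------------------------------------
  if (is.null(axis)) {
    debye <- 1 / cond$kappa
    iface <- unique(vapply(layers, function(l) l$r_out, 0))
    r0 <- layers[[1]]$r_in
    r_out_obj <- max(vapply(layers[seq_len(length(layers) - 1)],
                            function(l) l$r_out, 0), r0)
    sc <- control$mesh_scale
    h_surf <- sc * max(min(debye / 20, r_out_obj / 40), 2e-3)
    ## resolve a strong Gouy-Chapman layer at a charged inner surface
    if (!is.null(surface)) {
      sig0 <- abs(.surface_sigma_max(surface))
      if (sig0 > 0) {
        gc_len <- 1 / (2 * pi * lB * sig0)
        h_surf <- sc * max(min(h_surf / sc, gc_len / 3), 2e-3)
      }
    }
    h_max <- sc * min(debye / 4, 5)
    anchors <- c(r0, iface)
    h_anch <- rep(h_surf, length(anchors))
    if (geometry == "sphere" && r0 == 0) h_anch[1] <- sc * r_out_obj / 40
    axis <- graded_axis(anchors, h_anch, growth = 0.35, h_max = h_max)
  }
  r <- axis
  n <- length(r)
  rf <- (r[-1] + r[-n]) / 2                    # interior face positions
  dr <- diff(r)

  ## face areas and CV boundaries
  face_lo <- c(r[1], rf)                        # CV inner bounds
  face_hi <- c(rf, r[n])                        # CV outer bounds
  if (geometry == "sphere") {
    area_f <- 4 * pi * rf^2
    vol_of <- function(a, b) (4 * pi / 3) * (pmax(b, a)^3 - a^3)
    area_at <- function(x) 4 * pi * x^2
  } else {
    area_f <- 2 * pi * rf
    vol_of <- function(a, b) pi * (pmax(b, a)^2 - a^2)
    area_at <- function(x) 2 * pi * x
  }

  ## face dielectric from the layer containing each face
  eps_face <- vapply(rf, function(x) {
    for (l in layers) if (x >= l$r_in && x <= l$r_out) return(l$eps_rel)
    1
  }, 0)
  cond_f <- area_f * eps_face / dr              # face conductances

  ## per-layer CV overlap volumes
  overlap <- function(l) {
    a <- pmin(pmax(face_lo, l$r_in), l$r_out)
    b <- pmin(pmax(face_hi, l$r_in), l$r_out)
    ifelse(b > a, vol_of(a, b), 0)
  }
  vol_ion <- rep(0, n)
  charged <- list()
  for (l in layers) {
    v <- overlap(l)
    if (l$source$type == "ions") vol_ion <- vol_ion + v
    else if (l$source$type != "none") charged <- c(charged, list(list(l = l, v = v)))
  }

  ## surface-charge node (inner boundary)
  surf_area <- if (!is.null(surface)) area_at(r[1]) else 0

  ## --- source terms ----------------------------------------------------------
  ## returns list(q = node charge in e (4 pi lB factor applied later),
  ##              dq = d(charge)/d(psi))
  vol_charge <- function(psi, scale) {
    q <- rep(0, n); dq <- rep(0, n)
    for (ch in charged) {
      src <- ch$l$source
      if (src$type == "fixed") {
        q <- q + scale * src$density * ch$v
      } else {                                  # regulated
        gs <- src$groups
        for (k in seq_along(gs$groups)) {
          g <- gs$groups[[k]]
          al <- ionization_fraction(g, cond$pH, psi, src$phi_s[k], src$phi_0)
          rho <- scale * src$densities[k]
          q <- q + rho * g$valence * al * ch$v
          dq <- dq + rho * g$valence * .dalpha_dpsi(al, g$valence) * ch$v
        }
      }
    }
    if (!is.null(surface)) {
      s <- .surface_sigma(surface, cond, psi[1])
      q[1] <- q[1] + scale * s$sigma * surf_area
      dq[1] <- dq[1] + scale * s$dsigma * surf_area
    }
    list(q = q, dq = dq)
  }

  ## --- assembly ---------------------------------------------------------------
  i_idx <- c(seq_len(n - 1), 2:n, seq_len(n))
  j_idx <- c(2:n, seq_len(n - 1), seq_len(n))
  L_diag <- rep(0, n)
  L_diag[1:(n - 1)] <- L_diag[1:(n - 1)] + cond_f
  L_diag[2:n] <- L_diag[2:n] + cond_f
  ## M = -L + D(psi): SPD
  M_pattern <- function(dvals)
    Matrix::sparseMatrix(i = i_idx, j = j_idx,
                         x = c(-cond_f, -cond_f, L_diag + dvals), dims = c(n, n))

  residual <- function(psi, scale) {
    qq <- vol_charge(psi, scale)
    flux <- cond_f * (psi[-1] - psi[-n])
    div <- rep(0, n)
    div[1:(n - 1)] <- div[1:(n - 1)] + flux
    div[2:n] <- div[2:n] - flux
    div + 4 * pi * lB * qq$q - kap2 * sinh(pmin(pmax(psi, -60), 60)) * vol_ion
  }
  jac_D <- function(psi, scale) {
    qq <- vol_charge(psi, scale)
    kap2 * cosh(pmin(pmax(psi, -60), 60)) * vol_ion - 4 * pi * lB * qq$dq
  }

  ## --- nonlinear solve --------------------------------------------------------
  psi <- rep(0, n)
  iters <- 0L
  final_res <- NA_real_
  converged <- FALSE
  if (control$method == "newton") {
    for (scale in control$ramp) {
      ok <- FALSE
      for (it in seq_len(control$max_iter)) {
        iters <- iters + 1L
        Fv <- residual(psi, scale)
        M <- M_pattern(jac_D(psi, scale))
        delta <- as.numeric(Matrix::solve(M, Fv))
        mx <- max(abs(delta))
        if (mx > 2) delta <- delta * (2 / mx)
        ## line search on the residual norm
        lam <- 1
        f0 <- sqrt(sum(Fv^2))
        for (ls in 1:8) {
          psi_try <- psi + lam * delta
          f1 <- sqrt(sum(residual(psi_try, scale)^2))
          if (f1 <= f0 * (1 - 1e-4 * lam) || mx < control$tol) break
          lam <- lam / 2
        }
        psi <- psi + lam * delta
        final_res <- sqrt(sum(residual(psi, scale)^2))
        if (max(abs(lam * delta)) < control$tol) { ok <- TRUE; break }
      }
      if (!ok && max(abs(delta)) > 1e-6)
        stop("PB solver failed to converge (residual ", signif(final_res, 3),
             ")", call. = FALSE)
    }
    converged <- TRUE
  } else {
    ## damped Picard with Debye-Hueckel preconditioner: split
    ## sinh(psi) = psi + (sinh(psi) - psi) and lag the remainder
    M0 <- M_pattern(kap2 * vol_ion)
    omega <- 0.5
    for (it in seq_len(control$max_iter * 20)) {
      iters <- iters + 1L
      qq <- vol_charge(psi, 1)
      ps <- pmin(pmax(psi, -60), 60)
      rhs <- 4 * pi * lB * qq$q - kap2 * (sinh(ps) - ps) * vol_ion
      psi_new <- as.numeric(Matrix::solve(M0, rhs))
      dmax <- max(abs(psi_new - psi))
      psi <- psi + omega * (psi_new - psi)
      if (omega * dmax < control$tol * 10) { converged <- TRUE; break }
    }
    final_res <- sqrt(sum(residual(psi, 1)^2))
    if (!converged)
      stop("Picard iteration failed to converge", call. = FALSE)
  }

  structure(list(r = r, psi = psi, geometry = geometry, cond = cond,
                 layers = layers, surface = surface,
                 vol_ion = vol_ion, charged = charged,
                 eps_face = eps_face, cond_f = cond_f,
                 surf_area = surf_area,
                 diagnostics = list(iterations = iters,
                                    final_residual = final_res,
                                    converged = converged, nodes = n)),
            class = c("pb_field_1d", "pb_field"))
}

## surface-charge helpers ------------------------------------------------------
.surface_sigma_max <- function(surface) {
  if (surface$type == "fixed") return(surface$sigma)
  sum(surface$sigmas * vapply(surface$groups$groups, function(g) g$valence, 0))
}
.surface_sigma <- function(surface, cond, psi) {
  if (surface$type == "fixed") return(list(sigma = surface$sigma, dsigma = 0))
  gs <- surface$groups
  sig <- 0; dsig <- 0
  for (k in seq_along(gs$groups)) {
    g <- gs$groups[[k]]
    al <- ionization_fraction(g, cond$pH, psi, surface$phi_s[k], surface$phi_0)
    sig <- sig + surface$sigmas[k] * g$valence * al
    dsig <- dsig + surface$sigmas[k] * g$valence * .dalpha_dpsi(al, g$valence)
  }
  list(sigma = sig, dsigma = dsig)
}

## ---------------------------------------------------------------------------

#' Solve the regulated sphere problem
#'
#' Couples the interior Poisson equation of a uniform dielectric sphere
#' carrying regulating volume charge to the nonlinear Poisson-Boltzmann
#' equation of the surrounding electrolyte. The ionization state of every
#' group responds self-consistently to the local potential and to its Born
#' solvation penalty; the solve uses damped Newton iteration on a graded
#' radial finite-volume mesh truncated `control$domain_factor` Debye
#' lengths beyond the surface.
#'
#' @param model a [sphere_model()].
#' @param cond a [solution_conditions()].
#' @param control a [pb_control()].
#' @param axis optional explicit node vector (overrides mesh generation).
#' @return A `pb_field_1d` object (radial nodes, dimensionless potential,
#'   convergence diagnostics).
#' @export
solve_sphere <- function(model, cond, control = pb_control(), axis = NULL) {
  stopifnot(inherits(model, "sphere_model"), inherits(cond, "solution_conditions"))
  R <- model$radius
  Vp <- 4 * pi * R^3 / 3
  gs <- model$groups
  phi_s <- if (model$born_on) {
    vapply(gs$groups, function(g)
      born_term(model$interior_dielectric, cond, g$ion_radius,
                model$born_attenuation), 0)
  } else rep(0, length(gs$groups))
  layers <- list(
    list(r_in = 0, r_out = R,
         eps_rel = model$interior_dielectric / cond$solvent_dielectric,
         source = list(type = "regulated", groups = gs,
                       densities = gs$counts / Vp, phi_s = phi_s,
                       phi_0 = model$phi_0)),
    list(r_in = R, r_out = R + control$domain_factor / cond$kappa,
         eps_rel = 1, source = list(type = "ions")))
  .pb_radial_solve(layers, cond, "sphere", control = control, axis = axis)
}

#' Solve the infinite-cylinder problem
#'
#' Nonlinear Poisson-Boltzmann equation in the annular electrolyte outside
#' an infinitely long cylinder whose surface carries either regulating
#' ionizable groups or a fixed charge density. The cylinder is hollow: no
#' interior domain enters and no interior dielectric constant is needed.
#' All quantities are per unit length.
#'
#' @param model a [cylinder_model()] (length may be `Inf`; a finite length
#'   only sets the per-group surface densities).
#' @param cond a [solution_conditions()].
#' @param control a [pb_control()].
#' @param axis optional explicit node vector.
#' @return A `pb_field_1d` object.
#' @export
solve_cylinder_infinite <- function(model, cond, control = pb_control(),
                                    axis = NULL) {
  stopifnot(inherits(model, "cylinder_model"), inherits(cond, "solution_conditions"))
  R <- model$radius
  if (model$regulation_enabled) {
    gs <- model$surface_groups
    area <- if (is.finite(model$length))
      .cylinder_area(R, model$length) else 2 * pi * R  # per nm
    surface <- list(type = "regulated", groups = gs,
                    sigmas = gs$counts / area,
                    phi_s = rep(0, length(gs$groups)),  # solvent-exposed
                    phi_0 = 0)
  } else {
    area <- if (is.finite(model$length))
      .cylinder_area(R, model$length) else stop(
        "constant_charge requires a finite length to define sigma", call. = FALSE)
    surface <- list(type = "fixed", sigma = model$constant_charge / area)
  }
  layers <- list(
    list(r_in = R, r_out = R + control$domain_factor / cond$kappa,
         eps_rel = 1, source = list(type = "ions")))
  .pb_radial_solve(layers, cond, "cylinder", surface = surface,
                   control = control, axis = axis)
}

#' Solve the core-shell sphere problem
#'
#' Three-domain radial solve for the buried-residue pKa model: a
#' low-dielectric core housing one regulating ionizable group (charge
#' smeared over the core volume, Born penalty from the core dielectric with
#' attenuation p), a shell carrying the protein background charge as a
#' fixed uniform density, and the electrolyte.
#'
#' @param model a [core_shell_model()].
#' @param cond a [solution_conditions()].
#' @param shell_charge override of the shell charge for this solve (e);
#'   default taken from the model (or its shell composition at this pH).
#' @param include_core_group if `FALSE`, the core layer carries no charge:
#'   the solve then yields the environment potential used to titrate the
#'   residue without its smeared-charge self-interaction (see
#'   [core_shell_pka()]).
#' @param control a [pb_control()].
#' @return A `pb_field_1d` object.
#' @export
solve_core_shell <- function(model, cond, shell_charge = NULL,
                             include_core_group = TRUE,
                             control = pb_control()) {
  stopifnot(inherits(model, "core_shell_model"))
  rc <- model$core_radius; Ro <- model$outer_radius
  Vc <- 4 * pi * rc^3 / 3
  Vs <- 4 * pi * (Ro^3 - rc^3) / 3
  if (is.null(shell_charge)) {
    shell_charge <- if (!is.null(model$shell_groups))
      structural_charge(model$shell_groups, cond$pH) else model$shell_charge
  }
  g <- model$core_group
  phi_s <- born_term(model$core_dielectric, cond, g$ion_radius,
                     model$born_attenuation)
  core_source <- if (include_core_group)
    list(type = "regulated", groups = group_set(list(g), 1),
         densities = 1 / Vc, phi_s = phi_s, phi_0 = 0)
  else list(type = "fixed", density = 0)
  layers <- list(
    list(r_in = 0, r_out = rc,
         eps_rel = model$core_dielectric / cond$solvent_dielectric,
         source = core_source),
    list(r_in = rc, r_out = Ro,
         eps_rel = model$shell_dielectric / cond$solvent_dielectric,
         source = list(type = "fixed", density = shell_charge / Vs)),
    list(r_in = Ro, r_out = Ro + control$domain_factor / cond$kappa,
         eps_rel = 1, source = list(type = "ions")))
  .pb_radial_solve(layers, cond, "sphere", control = control)
}

#' @export
print.pb_field_1d <- function(x, ...) {
  cat(sprintf("1-D radial PB field (%s): %d nodes, %d iterations, residual %.3g\n",
              x$geometry, x$diagnostics$nodes, x$diagnostics$iterations,
              x$diagnostics$final_residual))
  cat(sprintf("  psi range [%.4g, %.4g], outer boundary psi = %.3g\n",
              min(x$psi), max(x$psi), x$psi[length(x$psi)]))
  invisible(x)
}
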