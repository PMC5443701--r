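## 2-D finite-volume solvers for the nonlinear Poisson-Boltzmann equation
## in a parallel-plate slit (or open box) containing constant-charge,
## ion-excluding objects, used by the charge renormalization machinery.
##
## Two metrics share one damped-Newton kernel:
##  * axisymmetric (r, z): sphere or finite cylinder on the symmetry axis,
##    walls at z = 0 and z = height perpendicular to the axis;
##  * planar (y, z): an infinite cylinder lying parallel to the walls
##    (translational invariance along its axis), all quantities per unit
##    length of cylinder.
## The dielectric constant is uniform (eps_m) everywhere -- appropriate for
## hollow objects at constant charge -- and objects exclude ions. All
## charges in e, potentials dimensionless, lengths nm.

## object descriptors (internal)
.axi_sphere <- function(zc, R, Q) list(type = "sphere", zc = zc, R = R, Q = Q)
.axi_cylinder <- function(zc, R, L, Q)
  list(type = "cylinder", zc = zc, R = R, L = L, Q = Q)
## infinite cylinder parallel to the walls; lambda = charge per nm (signed)
.planar_circle <- function(zc, R, lambda)
  list(type = "circle", zc = zc, R = R, lambda = lambda)

## ---------------------------------------------------------------------------
## shared Newton kernel: solves L psi + 4 pi lB q - kappa^2 sinh(psi) V_e = 0
.pb2d_newton <- function(L, q_v, vol_e_v, cond, control) {
  n <- length(q_v)
  lB <- cond$lB; kap2 <- cond$kappa^2
  clamp <- function(p) pmin(pmax(p, -60), 60)
  residual <- function(psi, scale)
    as.numeric(L %*% psi) + 4 * pi * lB * scale * q_v -
      kap2 * sinh(clamp(psi)) * vol_e_v
  psi <- rep(0, n)
  iters <- 0L; final_res <- NA_real_
  for (scale in control$ramp) {
    ok <- FALSE
    delta <- rep(Inf, n)
    for (it in seq_len(control$max_iter)) {
      iters <- iters + 1L
      Fv <- residual(psi, scale)
      D <- kap2 * cosh(clamp(psi)) * vol_e_v
      M <- -L + Matrix::Diagonal(n, x = D)
      delta <- as.numeric(Matrix::solve(M, Fv))
      mx <- max(abs(delta))
      if (mx > 2) delta <- delta * (2 / mx)
      lam <- 1
      f0 <- sqrt(sum(Fv^2))
      for (ls in 1:8) {
        f1 <- sqrt(sum(residual(psi + lam * delta, scale)^2))
        if (f1 <= f0 * (1 - 1e-4 * lam) || mx < control$tol) break
        lam <- lam / 2
      }
      psi <- psi + lam * delta
      if (max(abs(lam * delta)) < control$tol) { ok <- TRUE; break }
    }
    final_res <- sqrt(sum(residual(psi, scale)^2))
    if (!ok && max(abs(delta)) > 1e-6)
      stop("2-D PB solve failed to converge (residual ",
           signif(final_res, 3), ")", call. = FALSE)
  }
  list(psi = psi, iterations = iters, final_residual = final_res)
}

## CV half-widths along an axis
.cv_bounds <- function(x) {
  n <- length(x)
  list(lo = c(x[1], (x[-1] + x[-n]) / 2), hi = c((x[-1] + x[-n]) / 2, x[n]))
}

## ---------------------------------------------------------------------------
## axisymmetric geometry

.axi_axes <- function(objects, cond, height, r_max, wall_sigma,
                      control = pb_control()) {
  debye <- 1 / cond$kappa
  sc <- control$mesh_scale
  h_max <- sc * debye / 4
  h_wall <- sc * min(debye / 12, height / 40)
  r_anch <- c(0); r_h <- c(min(h_max, sc * r_max / 30))
  z_anch <- c(0, height); z_h <- c(h_wall, h_wall)
  for (ob in objects) {
    area <- if (ob$type == "sphere") 4 * pi * ob$R^2 else
      .cylinder_area(ob$R, ob$L)
    sig <- abs(ob$Q) / area
    gc_len <- if (sig > 0) 1 / (2 * pi * cond$lB * sig) else Inf
    h_obj <- sc * max(min(gc_len / 3, debye / 15, ob$R / 10), 2.5e-3)
    if (ob$type == "sphere") {
      h_body <- sc * ob$R / 12
      r_anch <- c(r_anch, ob$R); r_h <- c(r_h, min(h_obj, h_body))
      z_anch <- c(z_anch, ob$zc - ob$R, ob$zc, ob$zc + ob$R)
      z_h <- c(z_h, min(h_obj, h_body), h_body, min(h_obj, h_body))
    } else {
      r_anch <- c(r_anch, ob$R); r_h <- c(r_h, h_obj)
      z_anch <- c(z_anch, ob$zc - ob$L / 2, ob$zc + ob$L / 2)
      z_h <- c(z_h, h_obj, h_obj)
    }
  }
  r_anch <- c(r_anch, r_max); r_h <- c(r_h, h_max)
  list(r = graded_axis(r_anch, r_h, growth = 0.35, h_max = h_max),
       z = graded_axis(z_anch, z_h, growth = 0.35, h_max = h_max))
}

## electrolyte volume fraction of each CV (axisymmetric)
.axi_fractions <- function(r, z, objects) {
  nr <- length(r); nz <- length(z)
  rb <- .cv_bounds(r); zb <- .cv_bounds(z)
  frac <- matrix(1, nr, nz)
  gx <- c(-0.3873, 0, 0.3873)
  for (ob in objects) {
    if (ob$type == "cylinder") {
      wr <- pmax(0, pmin(rb$hi, ob$R)^2 - pmin(rb$lo, ob$R)^2) /
        (rb$hi^2 - rb$lo^2)
      z1 <- ob$zc - ob$L / 2; z2 <- ob$zc + ob$L / 2
      wz <- pmax(0, pmin(zb$hi, z2) - pmax(zb$lo, z1)) / (zb$hi - zb$lo)
      frac <- frac - outer(wr, wz)
    } else {
      rin <- which(rb$lo < ob$R)
      zin <- which(zb$hi > ob$zc - ob$R & zb$lo < ob$zc + ob$R)
      for (i in rin) {
        rs <- (rb$lo[i] + rb$hi[i]) / 2 + gx * (rb$hi[i] - rb$lo[i])
        wr_s <- rs / sum(rs)            # radial measure weight (dV ~ r dr)
        for (j in zin) {
          zs <- (zb$lo[j] + zb$hi[j]) / 2 + gx * (zb$hi[j] - zb$lo[j])
          m <- outer(rs^2, (zs - ob$zc)^2, "+") < ob$R^2
          frac[i, j] <- frac[i, j] - sum(wr_s * rowMeans(m))
        }
      }
    }
  }
  pmin(pmax(frac, 0), 1)
}

## deposit surface + wall charges onto nodes (axisymmetric): matrix in e
.axi_charges <- function(r, z, objects, wall_sigma) {
  nr <- length(r); nz <- length(z)
  rb <- .cv_bounds(r); zb <- .cv_bounds(z)
  ring <- pi * (rb$hi^2 - rb$lo^2)
  q <- matrix(0, nr, nz)
  if (wall_sigma != 0) {
    q[, 1] <- q[, 1] + wall_sigma * ring
    q[, nz] <- q[, nz] + wall_sigma * ring
  }
  for (ob in objects) {
    if (ob$Q == 0) next
    if (ob$type == "cylinder") {
      z1 <- ob$zc - ob$L / 2; z2 <- ob$zc + ob$L / 2
      sig <- ob$Q / .cylinder_area(ob$R, ob$L)
      iR <- which.min(abs(r - ob$R))
      dz_in <- pmax(0, pmin(zb$hi, z2) - pmax(zb$lo, z1))
      q[iR, ] <- q[iR, ] + sig * 2 * pi * ob$R * dz_in
      for (jz in c(which.min(abs(z - z1)), which.min(abs(z - z2)))) {
        cap <- pi * pmax(0, pmin(rb$hi, ob$R)^2 - pmin(rb$lo, ob$R)^2)
        q[, jz] <- q[, jz] + sig * cap
      }
    } else {
      ## Fibonacci lattice on the sphere, bilinear deposition
      npt <- 4000
      k <- seq_len(npt) - 0.5
      cth <- 1 - 2 * k / npt
      rp <- ob$R * sqrt(pmax(0, 1 - cth^2))
      zp <- ob$zc + ob$R * cth
      q <- q + .bilinear_deposit(r, z, rp, zp, rep(ob$Q / npt, npt))
    }
  }
  q
}

.bilinear_deposit <- function(x, z, xp, zp, qp) {
  nx <- length(x); nz <- length(z)
  q <- matrix(0, nx, nz)
  ix <- pmin(pmax(findInterval(xp, x), 1), nx - 1)
  iz <- pmin(pmax(findInterval(zp, z), 1), nz - 1)
  tx <- (xp - x[ix]) / (x[ix + 1] - x[ix])
  tz <- (zp - z[iz]) / (z[iz + 1] - z[iz])
  for (pp in seq_along(qp)) {
    i <- ix[pp]; j <- iz[pp]; a <- tx[pp]; b <- tz[pp]
    q[i, j] <- q[i, j] + qp[pp] * (1 - a) * (1 - b)
    q[i + 1, j] <- q[i + 1, j] + qp[pp] * a * (1 - b)
    q[i, j + 1] <- q[i, j + 1] + qp[pp] * (1 - a) * b
    q[i + 1, j + 1] <- q[i + 1, j + 1] + qp[pp] * a * b
  }
  q
}

#' Solve the axisymmetric constant-charge PB problem
#'
#' Finite-volume damped-Newton solve of the nonlinear Poisson-Boltzmann
#' equation on a graded tensor-product (r, z) mesh, for constant-charge
#' ion-excluding objects (sphere or finite cylinder centred on the
#' symmetry axis) in a parallel-plate slit with constant wall surface
#' charge. Pass `wall_sigma = 0` for an isolated object and an empty
#' `objects` list for the bare slit; supply the same `axes` to related
#' runs so that discretization errors cancel in free-energy differences.
#'
#' @param objects list of object descriptors, each
#'   `list(type = "sphere", zc =, R =, Q =)` or
#'   `list(type = "cylinder", zc =, R =, L =, Q =)` (charges in e, signed).
#' @param cond a [solution_conditions()].
#' @param height slit height 2h in nm (wall to wall).
#' @param r_max lateral truncation radius in nm.
#' @param wall_sigma wall surface charge density in e/nm^2 (both walls).
#' @param control a [pb_control()].
#' @param axes optional list(r =, z =) of node vectors.
#' @return A `pb_field_2d` object (axes, potential matrix `psi`,
#'   electrolyte volumes `vol_ion`, node charges `q_node`, face
#'   conductances, diagnostics).
#' @export
solve_axisymmetric <- function(objects, cond, height, r_max, wall_sigma = 0,
                               control = pb_control(), axes = NULL) {
  stopifnot(inherits(cond, "solution_conditions"))
  for (ob in objects) {
    half <- if (ob$type == "sphere") ob$R else ob$L / 2
    if (ob$zc - half <= 0 || ob$zc + half >= height)
      stop("object intersects a wall", call. = FALSE)
  }
  if (is.null(axes))
    axes <- .axi_axes(objects, cond, height, r_max, wall_sigma, control)
  r <- axes$r; z <- axes$z
  nr <- length(r); nz <- length(z)
  rb <- .cv_bounds(r); zb <- .cv_bounds(z)
  ann <- pi * (rb$hi^2 - rb$lo^2)
  dz_cv <- zb$hi - zb$lo
  vol_cv <- outer(ann, dz_cv)
  frac <- .axi_fractions(r, z, objects)
  q_node <- .axi_charges(r, z, objects, wall_sigma)
  ## face conductances
  rmid <- (r[-1] + r[-nr]) / 2
  cr <- outer(2 * pi * rmid / diff(r), dz_cv)        # (nr-1) x nz
  cz <- outer(ann, 1 / diff(z))                      # nr x (nz-1)
  .pb2d_assemble_and_solve(r, z, cr, cz, frac * vol_cv, q_node, cond, control,
                           extra = list(objects = objects,
                                        wall_sigma = wall_sigma,
                                        height = height, r_max = r_max,
                                        metric = "axisymmetric"))
}

#' Solve the planar slit problem with an infinite parallel cylinder
#'
#' Translationally invariant version of the slit problem: an infinite
#' cylinder of radius R lies parallel to the walls at the slit mid-plane,
#' carrying a constant line charge density (e per nm). The cross-section
#' (y, z) is solved on a graded tensor mesh; all extensive quantities
#' (charges, free energies) are per unit length of cylinder. Used for the
#' quasi-infinite polyelectrolyte limit of the renormalization procedure.
#'
#' @param circle object descriptor `list(type = "circle", zc =, R =,
#'   lambda =)` with `lambda` the line charge in e/nm, or `NULL` for the
#'   bare slit.
#' @param cond a [solution_conditions()].
#' @param height slit height 2h in nm.
#' @param y_max lateral truncation half-width in nm (domain spans
#'   [-y_max, y_max]).
#' @param wall_sigma wall surface charge density in e/nm^2.
#' @param control a [pb_control()].
#' @param axes optional list(r =, z =) node vectors (`r` is the y axis).
#' @return A `pb_field_2d` object; free energies from it are per nm.
#' @export
solve_planar_slit <- function(circle, cond, height, y_max, wall_sigma = 0,
                              control = pb_control(), axes = NULL) {
  stopifnot(inherits(cond, "solution_conditions"))
  objects <- if (is.null(circle)) list() else list(circle)
  for (ob in objects)
    if (ob$zc - ob$R <= 0 || ob$zc + ob$R >= height)
      stop("object intersects a wall", call. = FALSE)
  if (is.null(axes))
    axes <- .planar_axes(objects, cond, height, y_max, control)
  y <- axes$r; z <- axes$z
  ny <- length(y); nz <- length(z)
  yb <- .cv_bounds(y); zb <- .cv_bounds(z)
  dy_cv <- yb$hi - yb$lo
  dz_cv <- zb$hi - zb$lo
  vol_cv <- outer(dy_cv, dz_cv)
  frac <- .planar_fractions(y, z, objects)
  q_node <- .planar_charges(y, z, objects, wall_sigma)
  cy <- outer(1 / diff(y), dz_cv)                    # (ny-1) x nz
  cz <- outer(dy_cv, 1 / diff(z))                    # ny x (nz-1)
  .pb2d_assemble_and_solve(y, z, cy, cz, frac * vol_cv, q_node, cond, control,
                           extra = list(objects = objects,
                                        wall_sigma = wall_sigma,
                                        height = height, r_max = y_max,
                                        metric = "planar"))
}

.planar_axes <- function(objects, cond, height, y_max, control) {
  debye <- 1 / cond$kappa
  sc <- control$mesh_scale
  h_max <- sc * debye / 4
  h_wall <- sc * min(debye / 12, height / 40)
  y_anch <- c(-y_max, y_max); y_h <- c(h_max, h_max)
  z_anch <- c(0, height); z_h <- c(h_wall, h_wall)
  for (ob in objects) {
    sig <- abs(ob$lambda) / (2 * pi * ob$R)
    gc_len <- if (sig > 0) 1 / (2 * pi * cond$lB * sig) else Inf
    h_obj <- sc * max(min(gc_len / 3, debye / 15, ob$R / 8), 2e-3)
    h_body <- sc * ob$R / 10
    y_anch <- c(y_anch, -ob$R, 0, ob$R)
    y_h <- c(y_h, min(h_obj, h_body), h_body, min(h_obj, h_body))
    z_anch <- c(z_anch, ob$zc - ob$R, ob$zc, ob$zc + ob$R)
    z_h <- c(z_h, min(h_obj, h_body), h_body, min(h_obj, h_body))
  }
  list(r = graded_axis(y_anch, y_h, growth = 0.35, h_max = h_max),
       z = graded_axis(z_anch, z_h, growth = 0.35, h_max = h_max))
}

.planar_fractions <- function(y, z, objects) {
  ny <- length(y); nz <- length(z)
  yb <- .cv_bounds(y); zb <- .cv_bounds(z)
  frac <- matrix(1, ny, nz)
  gx <- c(-0.3873, 0, 0.3873)
  for (ob in objects) {
    yin <- which(yb$hi > -ob$R & yb$lo < ob$R)
    zin <- which(zb$hi > ob$zc - ob$R & zb$lo < ob$zc + ob$R)
    for (i in yin) {
      ys <- (yb$lo[i] + yb$hi[i]) / 2 + gx * (yb$hi[i] - yb$lo[i])
      for (j in zin) {
        zs <- (zb$lo[j] + zb$hi[j]) / 2 + gx * (zb$hi[j] - zb$lo[j])
        m <- outer(ys^2, (zs - ob$zc)^2, "+") < ob$R^2
        frac[i, j] <- frac[i, j] - mean(m)
      }
    }
  }
  pmin(pmax(frac, 0), 1)
}

.planar_charges <- function(y, z, objects, wall_sigma) {
  ny <- length(y); nz <- length(z)
  yb <- .cv_bounds(y)
  q <- matrix(0, ny, nz)
  if (wall_sigma != 0) {
    q[, 1] <- q[, 1] + wall_sigma * (yb$hi - yb$lo)
    q[, nz] <- q[, nz] + wall_sigma * (yb$hi - yb$lo)
  }
  for (ob in objects) {
    if (ob$lambda == 0) next
    npt <- 2000
    th <- (seq_len(npt) - 0.5) / npt * 2 * pi
    q <- q + .bilinear_deposit(y, z, ob$R * sin(th), ob$zc + ob$R * cos(th),
                               rep(ob$lambda / npt, npt))
  }
  q
}

## assemble the FV operator from face conductance matrices and run Newton
.pb2d_assemble_and_solve <- function(x, z, cx, cz, vol_e, q_node, cond,
                                     control, extra) {
  nx <- length(x); nz <- length(z); n <- nx * nz
  idx <- function(i, j) i + (j - 1L) * nx
  ia <- as.vector(outer(seq_len(nx - 1), seq_len(nz), idx))
  ib <- as.vector(outer(2:nx, seq_len(nz), idx))
  cxv <- as.vector(cx)
  ja <- as.vector(outer(seq_len(nx), seq_len(nz - 1), idx))
  jb <- as.vector(outer(seq_len(nx), 2:nz, idx))
  czv <- as.vector(cz)
  ii <- c(ia, ib, ia, ib, ja, jb, ja, jb)
  jj <- c(ib, ia, ia, ib, jb, ja, ja, jb)
  xx <- c(cxv, cxv, -cxv, -cxv, czv, czv, -czv, -czv)
  L <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  sol <- .pb2d_newton(L, as.numeric(q_node), as.numeric(vol_e), cond, control)
  structure(c(list(r = x, z = z, psi = matrix(sol$psi, nx, nz),
                   vol_ion = vol_e, q_node = q_node, cond = cond,
                   faces = list(ia = c(ia, ja), ib = c(ib, jb),
                                cc = c(cxv, czv)),
                   diagnostics = list(iterations = sol$iterations,
                                      final_residual = sol$final_residual,
                                      converged = TRUE, nodes = n,
                                      nr = nx, nz = nz)),
              extra),
            class = c("pb_field_2d", "pb_field"))
}

#' @export
free_energy.pb_field_2d <- function(field) {
  ## discrete dual form of the constant-charge functional; see field.R
  if (!isTRUE(field$diagnostics$converged))
    stop("field is not converged; refusing to integrate", call. = FALSE)
  lB <- field$cond$lB
  psi <- as.numeric(field$psi)
  dpsi2 <- (psi[field$faces$ia] - psi[field$faces$ib])^2
  e_grad <- sum(field$faces$cc * dpsi2) / (8 * pi * lB)
  ps <- pmin(pmax(psi, -60), 60)
  e_ion <- sum(field$cond$kappa^2 * (cosh(ps) - 1) * as.numeric(field$vol_ion)) /
    (4 * pi * lB)
  sum(as.numeric(field$q_node) * psi) - e_grad - e_ion
}

#' @export
print.pb_field_2d <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("2-D %s PB field: %d x %d nodes, %d iterations, residual %.3g\n",
              x$metric, d$nr, d$nz, d$iterations, d$final_residual))
  cat(sprintf("  slit height %.3g nm, lateral extent %.3g nm, wall sigma %.4g e/nm^2, %d object(s)\n",
              x$height, x$r_max, x$wall_sigma, length(x$objects)))
  cat(sprintf("  psi range [%.4g, %.4g]\n", min(x$psi), max(x$psi)))
  invisible(x)
}
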