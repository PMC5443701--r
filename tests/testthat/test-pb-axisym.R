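## 2-D slit solvers (axisymmetric and planar): oracles and conservation.

test_that("the empty charged slit matches the single-wall superposition at mid-gap", {
  cond <- cond_100mM()
  debye <- 1 / cond$kappa
  h <- 4 * debye
  ## small wall charge: linear regime, psi_wall about -0.3
  sig <- -abs(pbcharge:::.wall_sigma_for_psi(cond, 0.3))
  f2 <- solve_axisymmetric(list(), cond, 2 * h, r_max = 5, wall_sigma = sig)
  p1 <- slit_profile(cond, 2 * h, sig)
  mid2 <- f2$psi[1, which.min(abs(f2$z - h))]
  super <- p1$psi_wall * (exp(-cond$kappa * h) + exp(-cond$kappa * h))
  expect_equal(mid2, super, tolerance = 0.03)
  ## and the fine 1-D profile agrees with the 2-D solve
  mid1 <- p1$psi[which.min(abs(p1$z - h))]
  expect_equal(mid2, mid1, tolerance = 0.01)
})

test_that("total ion charge balances object plus wall charge in the slit", {
  cond <- cond_100mM()
  debye <- 1 / cond$kappa
  ob <- pbcharge:::.axi_cylinder(zc = 5 * debye, R = 0.5, L = 2, Q = -20)
  sig <- -abs(pbcharge:::.wall_sigma_for_psi(cond, 0.5))
  f <- solve_axisymmetric(list(ob), cond, 10 * debye, r_max = 0.5 + 8 * debye,
                          wall_sigma = sig)
  q_fixed <- sum(f$q_node)
  expect_equal(ion_charge(f), -q_fixed, tolerance = 0.01)
})

test_that("an uncharged object in a charged slit contributes only the tiny depletion energy", {
  cond <- cond_100mM()
  debye <- 1 / cond$kappa
  h <- 4 * debye + 1
  sig <- -abs(pbcharge:::.wall_sigma_for_psi(cond, 0.5))
  ob <- pbcharge:::.axi_sphere(h, 1, 0)
  axes <- pbcharge:::.axi_axes(list(ob), cond, 2 * h, 1 + 8 * debye, sig,
                               pb_control())
  fA <- solve_axisymmetric(list(ob), cond, 2 * h, 1 + 8 * debye, sig,
                           axes = axes)
  fB <- solve_axisymmetric(list(), cond, 2 * h, 1 + 8 * debye, sig,
                           axes = axes)
  fC <- solve_axisymmetric(list(ob), cond, 2 * h, 1 + 8 * debye, 0,
                           axes = axes)
  Fos <- free_energy(fA) - free_energy(fB) - free_energy(fC)
  expect_lt(abs(Fos), 1e-3)
  expect_equal(free_energy(fC), 0, tolerance = 1e-10)
})

test_that("a long axial cylinder reproduces the infinite-cylinder mid-section potential", {
  cond <- cond_100mM()
  debye <- 1 / cond$kappa
  R <- 0.5; L <- 14 * debye
  lam <- -3                       # e per nm, moderate charge
  Qtot <- lam * L
  h <- 4 * debye + L / 2
  ob <- pbcharge:::.axi_cylinder(h, R, L, Qtot)
  f2 <- solve_axisymmetric(list(ob), cond, 2 * h, R + 8 * debye, 0)
  iR <- which.min(abs(f2$r - R)); iz <- which.min(abs(f2$z - h))
  ## infinite-cylinder solve at the same lateral surface charge density
  ## (the 2-D run spreads Q over lateral surface plus end caps)
  sig <- Qtot / (2 * pi * R * L + 2 * pi * R^2)
  m <- cylinder_model(R, 20 * debye,
                      constant_charge = sig *
                        (2 * pi * R * 20 * debye + 2 * pi * R^2))
  f1 <- solve_cylinder_infinite(m, cond)
  expect_equal(f2$psi[iR, iz], f1$psi[1],
               tolerance = 0.05)
})

test_that("the planar slit solver agrees with the radial solver for an isolated line charge", {
  cond <- cond_100mM()
  debye <- 1 / cond$kappa
  R <- 0.3; lam <- -2
  h <- 6 * debye + R
  circ <- pbcharge:::.planar_circle(h, R, lam)
  fp <- solve_planar_slit(circ, cond, 2 * h, R + 8 * debye, 0)
  ## mean surface potential from the planar field: sample the circle
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  pts_y <- R * sin(th); pts_z <- h + R * cos(th)
  psi_i <- numeric(length(th))
  for (k in seq_along(th)) {
    iy <- which.min(abs(fp$r - pts_y[k])); iz <- which.min(abs(fp$z - pts_z[k]))
    psi_i[k] <- fp$psi[iy, iz]
  }
  m <- cylinder_model(R, 20 * debye,
                      constant_charge = lam / (2 * pi * R) *
                        (2 * pi * R * 20 * debye + 2 * pi * R^2))
  f1 <- solve_cylinder_infinite(m, cond)
  expect_equal(mean(psi_i), f1$psi[1], tolerance = 0.07)
})

test_that("halving all mesh scales leaves the slit free energy and the extracted charge converged", {
  cond <- cond_100mM()
  debye <- 1 / cond$kappa
  h <- 4 * debye + 1
  sig <- -abs(pbcharge:::.wall_sigma_for_psi(cond, 0.5))
  ## grid-aligned cylinder: the raw free energy itself is converged
  ob <- pbcharge:::.axi_cylinder(h, 0.5, 2, -5)
  F1 <- free_energy(solve_axisymmetric(list(ob), cond, 2 * h, 0.5 + 8 * debye,
                                       sig, pb_control(mesh_scale = 1)))
  F2 <- free_energy(solve_axisymmetric(list(ob), cond, 2 * h, 0.5 + 8 * debye,
                                       sig, pb_control(mesh_scale = 0.5)))
  expect_equal(F2 / F1, 1, tolerance = 0.01)
  ## sphere surfaces are staircase-represented: their raw self-energy
  ## converges only linearly, but it cancels in the three-run difference,
  ## so the extracted effective charge is the converged quantity
  gs <- group_set(list(acid_group(4)), 2)
  ms <- sphere_model(1, 78.5, gs, born_on = FALSE)
  e1 <- effective_charge(ms, cond, charge = -2)$q_eff
  e2 <- effective_charge(ms, cond, charge = -2,
                         control = pb_control(mesh_scale = 0.5))$q_eff
  expect_equal(e2 / e1, 1, tolerance = 0.01)
})
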