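## Effective (interaction) charge machinery: limits, invariances,
## far-field consistency.

test_that("the bare-slit mean virtual-surface potential behaves linearly and vanishes without walls", {
  cond <- cond_100mM()
  debye <- 1 / cond$kappa
  gs <- group_set(list(acid_group(4)), 1)
  m <- sphere_model(0.3, 78.5, gs, born_on = FALSE)
  slit0 <- slit_geometry(4 * debye + 0.3, 0)
  expect_equal(slit_reference_potential(slit0, cond, m), 0)
  ## point-like object: mean approaches the mid-plane superposition value
  sig <- -abs(pbcharge:::.wall_sigma_for_psi(cond, 0.2))
  slit <- slit_geometry(4 * debye + 0.3, sig)
  v <- slit_reference_potential(slit, cond, m)
  p1 <- slit_profile(cond, 2 * slit$half_height, sig)
  mid <- p1$psi_wall * 2 * exp(-cond$kappa * slit$half_height)
  expect_equal(v, mid, tolerance = 0.03)
  ## doubling a small wall charge doubles the mean potential
  slit2 <- slit_geometry(4 * debye + 0.3, 2 * sig)
  expect_equal(slit_reference_potential(slit2, cond, m), 2 * v,
               tolerance = 0.02)
  ## a surface poking into the walls is refused
  expect_error(slit_reference_potential(slit_geometry(0.2, sig), cond, m),
               "intersects")
})

test_that("weakly charged, weakly screened objects are not renormalized", {
  ## kappa R well below 1: eta_n returns to unity
  cond <- solution_conditions(7, 0.01)
  gs <- group_set(list(acid_group(4)), 1)
  m <- sphere_model(1, 78.5, gs, born_on = FALSE)
  ec <- effective_charge(m, cond, charge = -0.5)
  expect_equal(ec$eta_n, 1, tolerance = 0.05)
})

test_that("the interaction free energy matches e Q <psi'> for small Q and drops below it for large Q", {
  cond <- solution_conditions(7, 0.01)
  gs <- group_set(list(acid_group(4)), 1)
  m <- sphere_model(1, 78.5, gs, born_on = FALSE)
  small <- interaction_free_energy(m, cond, charge = -0.5)
  expect_equal(small$F_os, small$Q * small$mean_virtual_potential,
               tolerance = 0.05)
  big <- interaction_free_energy(m, cond, charge = -40)
  expect_lt(big$F_os, big$Q * big$mean_virtual_potential)
})

test_that("q_eff is insensitive to the gap and to the wall charge", {
  cond <- cond_100mM()
  m <- cylinder_model(0.5, 4, constant_charge = -25)
  ec <- effective_charge(m, cond, sensitivity = TRUE)
  s <- ec$sensitivity
  expect_lt(max(abs(s / s["4"] - 1)), 0.05)  # kappa z* in {3, 4, 5}
  ## halving the wall charge (still linear walls) barely moves q_eff
  ec_half <- effective_charge(m, cond, slit_config(psi_wall = 0.25))
  expect_equal(ec_half$q_eff / ec$q_eff, 1, tolerance = 0.05)
})

test_that("the renormalization factor decreases monotonically with charge magnitude", {
  cond <- cond_100mM()
  etas <- vapply(c(5, 25, 80), function(Q) {
    m <- cylinder_model(0.5, 4, constant_charge = -Q)
    effective_charge(m, cond)$eta_n
  }, 0)
  expect_true(all(diff(etas) < 0))
})

test_that("two weak spheres interact with the screened-Coulomb energy of their effective charges", {
  ## far-field check: F_pair(d) - F_A - F_B = qeff^2 lB exp(-kappa d)/d
  cond <- cond_100mM()
  debye <- 1 / cond$kappa
  R <- 0.3; Q <- -1
  d <- 3.2 * debye
  height <- 2 * d + 8 * debye
  zc <- height / 2
  r_max <- R + 8 * debye
  obA <- pbcharge:::.axi_sphere(zc - d / 2, R, Q)
  obB <- pbcharge:::.axi_sphere(zc + d / 2, R, Q)
  axes <- pbcharge:::.axi_axes(list(obA, obB), cond, height, r_max, 0,
                               pb_control())
  Fpair <- free_energy(solve_axisymmetric(list(obA, obB), cond, height,
                                          r_max, 0, axes = axes))
  FA <- free_energy(solve_axisymmetric(list(obA), cond, height, r_max, 0,
                                       axes = axes))
  FB <- free_energy(solve_axisymmetric(list(obB), cond, height, r_max, 0,
                                       axes = axes))
  F_int <- Fpair - FA - FB
  F_dh <- Q^2 * cond$lB * exp(-cond$kappa * d) / d /
    (1 + cond$kappa * R)^2 * exp(2 * cond$kappa * R)
  expect_equal(F_int, F_dh, tolerance = 0.15)
})

test_that("uncharged walls make the interaction charge undefined, loudly", {
  cond <- cond_100mM()
  m <- cylinder_model(0.5, 4, constant_charge = -10)
  expect_error(effective_charge(m, cond, slit_config(wall_sigma = 0)),
               "undefined")
})
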