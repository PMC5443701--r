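## Closed-form physical quantities: lengths, ionization chemistry,
## regulation thresholds, condensation comparators.

test_that("Bjerrum length matches direct CODATA evaluation and scales inversely with dielectric", {
  ## independent evaluation of e^2 / (4 pi eps eps0 kB T) in nm
  e <- 1.602176634e-19; kB <- 1.380649e-23; eps0 <- 8.8541878128e-12
  lB_water <- e^2 / (4 * pi * 78.5 * eps0 * kB * 298.15) * 1e9
  expect_equal(bjerrum_length(78.5), lB_water, tolerance = 1e-12)
  expect_equal(lB_water, 0.714, tolerance = 1e-3)
  expect_equal(bjerrum_length(40), lB_water * 78.5 / 40, tolerance = 1e-12)
  expect_equal(bjerrum_length(40), 1.40, tolerance = 1e-2)
  ## exact inverse proportionality
  expect_equal(bjerrum_length(39.25) / bjerrum_length(78.5), 2)
  expect_error(bjerrum_length(-1), "positive")
  expect_error(bjerrum_length(78.5, 0), "positive")
})

test_that("Debye length reproduces the 100 mM value and square-root scaling", {
  expect_equal(debye_length(cond_100mM()), 0.962, tolerance = 2e-3)
  ## c -> c/100 lengthens the screening length exactly 10x
  expect_equal(debye_length(solution_conditions(7, 0.001)) /
                 debye_length(cond_100mM()), 10, tolerance = 1e-12)
  expect_equal(debye_length(solution_conditions(7, 0.001)), 9.62,
               tolerance = 2e-2)
  expect_error(solution_conditions(7, 0), "positive")
  expect_error(solution_conditions(-1, 0.1), "pH")
})

test_that("ionization fraction reduces to Henderson-Hasselbalch and responds to potential and solvation", {
  asp <- acid_group(4)
  expect_equal(ionization_fraction(asp, pH = 4), 0.5)
  ## hand evaluation: z = -1, pH = pKa, psi = -ln 3 makes exp(z psi) = 3
  expect_equal(ionization_fraction(asp, pH = 4, psi_local = -log(3)),
               1 / (1 + 3))
  ## infinite burial penalty discharges the group
  expect_equal(ionization_fraction(asp, pH = 12, phi_s = 1e4), 0)
  expect_equal(ionization_fraction(base_group(), pH = 3, phi_s = 1e4), 0)
  ## saturates smoothly, never NaN (a deeply negative potential discharges
  ## an acid regardless of pH)
  expect_equal(ionization_fraction(asp, pH = 14, psi_local = -50), 0,
               tolerance = 1e-10)
  expect_error(ionization_fraction(asp, 7, phi_s = -1), "non-negative")
})

test_that("ionization fraction is monotone in phi_s for any group and in psi per group valence", {
  phis <- seq(0, 12, by = 0.5)
  psis <- seq(-4, 4, by = 0.25)
  for (g in list(acid_group(4), acid_group(8), base_group(10.4),
                 base_group(6))) {
    a_phi <- ionization_fraction(g, 7, 0, phis)
    expect_true(all(diff(a_phi) < 0))
    ## z psi in the Boltzmann factor: a falling potential discharges an
    ## acid (z = -1) and charges up a base, monotonically
    a_psi <- ionization_fraction(g, 7, psis)
    if (g$valence == -1) expect_true(all(diff(a_psi) > 0))
    else expect_true(all(diff(a_psi) < 0))
  }
})

test_that("Born term reproduces the carboxyl benchmark and clamps at zero", {
  cond <- cond_100mM()
  expect_equal(born_term(40, cond, 0.25), 1.4, tolerance = 0.05)
  expect_equal(born_term(78.5, cond, 0.25), 0)
  ## direct evaluation for a strongly apolar interior
  lB <- bjerrum_length(78.5)
  expect_equal(born_term(10, cond, 0.25),
               lB / 0.5 * (78.5 / 10 - 1), tolerance = 1e-12)
  expect_equal(born_term(10, cond, 0.25), 9.8, tolerance = 0.05)
  ## attenuation is multiplicative
  expect_equal(born_term(40, cond, 0.25, attenuation = 0.25),
               born_term(40, cond, 0.25) * 0.25)
  ## no dielectric contrast in reverse never goes negative
  expect_equal(born_term(100, solution_conditions(7, 0.1,
                                                  solvent_dielectric = 78.5),
                         0.25), 0)
  expect_error(born_term(40, cond, -0.1), "positive")
})

test_that("structural charge sums Henderson-Hasselbalch terms with signs", {
  gs1 <- group_set(list(acid_group(4)), 1)
  expect_equal(structural_charge(gs1, 4), -0.5)
  ## saturation limit
  gsQ <- group_set(list(acid_group(4)), 25)
  expect_equal(structural_charge(gsQ, 13), -25, tolerance = 1e-6)
  ## symmetric acid/base pair cancels exactly at the midpoint pH
  gs2 <- group_set(list(acid_group(4), base_group(10.4)), c(10, 10))
  expect_equal(structural_charge(gs2, 7.2), 0, tolerance = 1e-12)
  ## hand-summed value off the symmetry point
  a <- 1 / (1 + 10^(-(7 - 4))); b <- 1 / (1 + 10^(7 - 10.4))
  expect_equal(structural_charge(gs2, 7), 10 * (-a + b), tolerance = 1e-12)
  ## half the full-ionization charge at pH = pKa (single group type)
  expect_equal(structural_charge(gsQ, 4), -25 / 2)
})

test_that("threshold potential implements the chemistry term minus the Born penalty, floored at zero", {
  expect_equal(as.numeric(threshold_potential(7, 4, 0.95)),
               abs(log(10) * 3 + log(1 / 0.95 - 1)), tolerance = 1e-12)
  expect_equal(as.numeric(threshold_potential(7, 4, 0.95)), 3.96,
               tolerance = 5e-3)
  p0 <- threshold_potential(4, 4, 0.5)
  expect_equal(as.numeric(p0), 0)
  expect_false(any(attr(p0, "degenerate")))
  expect_equal(as.numeric(threshold_potential(7, 4, 0.95, phi_s = 1.4)),
               as.numeric(threshold_potential(7, 4, 0.95)) - 1.4)
  ## Born penalty exceeding the chemistry term flags degeneracy
  pd <- threshold_potential(4.5, 4, 0.9, phi_s = 5)
  expect_equal(as.numeric(pd), 0)
  expect_true(any(attr(pd, "degenerate")))
  expect_error(threshold_potential(7, 4, 1.2), "0, 1")
})

test_that("threshold charge solves the interior-potential criterion at equality", {
  cond <- cond_100mM()
  psi_t <- threshold_potential(7, 4, 0.95)
  ## full solve: substituting Q_t back reproduces psi_t to machine precision
  for (R in c(2.55, 5.1)) {
    tr <- threshold_charge(R, 40, cond, psi_t)
    lBp <- bjerrum_length(40); lBw <- cond$lB; kR <- cond$kappa * R
    lhs <- tr$Q_t / R * (lBp / 5 + lBw / (1 + kR))
    expect_equal(lhs, as.numeric(psi_t), tolerance = 1e-12)
    expect_equal(tr$dimensionless_criterion, tr$Q_t * lBp / R,
                 tolerance = 1e-12)
  }
  ## with the surface-potential contribution taken as 2 kBT the criterion is
  ## R-independent and about 10 (one significant figure)
  tr2 <- threshold_charge(2.55, 40, cond, psi_t, psi_s_assumed = 2)
  expect_equal(tr2$dimensionless_criterion, 5 * (as.numeric(psi_t) - 2),
               tolerance = 1e-12)
  expect_equal(signif(tr2$dimensionless_criterion, 1), 10)
  ## including the carboxyl Born penalty drops the criterion below 5
  psi_t3 <- threshold_potential(7, 4, 0.95, phi_s = 1.4)
  tr3 <- threshold_charge(2.55, 40, cond, psi_t3, psi_s_assumed = 2)
  expect_lt(tr3$dimensionless_criterion, 5)
  ## degenerate threshold propagates
  trd <- threshold_charge(2.55, 40, cond, threshold_potential(4.5, 4, 0.9,
                                                              phi_s = 5))
  expect_true(trd$degenerate)
  expect_equal(trd$Q_t, 0)
})

test_that("Debye-Hueckel sphere surface potential is linear in Q and matches the closed form", {
  cond <- cond_100mM()
  expect_equal(dh_sphere_surface_potential(0, 5.1, cond), 0)
  v <- dh_sphere_surface_potential(12.75, 5.1, cond)
  expect_equal(v, 12.75 * cond$lB / (5.1 * (1 + cond$kappa * 5.1)),
               tolerance = 1e-12)
  expect_equal(dh_sphere_surface_potential(25.5, 5.1, cond), 2 * v)
})

test_that("mean interior potential equals the quadrature of the parabolic profile", {
  ## oracle: psi(r) = (2 pi lB_p rho / 3) (R^2 - r^2) volume-averaged
  R <- 3.2; Q <- 7; eps_p <- 25
  lBp <- bjerrum_length(eps_p)
  rho <- Q / (4 * pi * R^3 / 3)
  r <- seq(0, R, length.out = 20001)
  prof <- (2 * pi * lBp * rho / 3) * (R^2 - r^2)
  w <- c(0.5, rep(1, length(r) - 2), 0.5)       # trapezoid weights
  avg <- sum(w * prof * r^2) / sum(w * r^2)
  expect_equal(mean_interior_potential(Q, R, eps_p), avg, tolerance = 1e-6)
  ## halving the interior dielectric doubles the mean potential
  expect_equal(mean_interior_potential(Q, R, eps_p / 2),
               2 * mean_interior_potential(Q, R, eps_p), tolerance = 1e-12)
  expect_equal(mean_interior_potential(0, R, eps_p), 0)
})

test_that("Manning fraction and the dsDNA line-charge parameter", {
  expect_equal(manning_fraction(4.2), 1 / 4.2, tolerance = 1e-12)
  expect_equal(manning_fraction(0.5), 1)
  expect_equal(manning_fraction(1), 1)
  xi <- dsdna_manning_parameter()
  expect_equal(xi, 4.2, tolerance = 0.1)
  ## doubling the rise halves the parameter
  expect_equal(dsdna_manning_parameter(rise_per_bp = 0.68), xi / 2,
               tolerance = 1e-12)
  ## parameter scales with the Bjerrum length of the medium
  c40 <- solution_conditions(7, 0.1, solvent_dielectric = 40)
  expect_equal(dsdna_manning_parameter(c40), xi * 78.5 / 40,
               tolerance = 1e-12)
})
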