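## 1-D radial regulated-sphere solver: limits, oracles, conservation.

test_that("a sphere with a vanishing inventory produces a flat field", {
  gs <- group_set(list(acid_group(4)), 1e-9)
  f <- solve_sphere(sphere_model(3, 40, gs), cond_100mM())
  expect_lt(max(abs(f$psi)), 1e-6)
})

test_that("a weakly charged sphere reproduces the Debye-Hueckel surface potential", {
  cond <- cond_100mM(pH = 9)
  gs <- group_set(list(acid_group(2)), 1)   # fully ionized single charge
  f <- solve_sphere(sphere_model(2, 78.5, gs, born_on = FALSE), cond)
  isurf <- which.min(abs(f$r - 2))
  expect_equal(f$psi[isurf], dh_sphere_surface_potential(-1, 2, cond),
               tolerance = 0.05)
})

test_that("the compact-protein benchmark regulates to about 78 percent", {
  cond <- cond_100mM()
  m <- regulation_benchmark_model()
  rep_ <- regulated_charge(m, cond)
  expect_equal(rep_$eta_g, 0.78, tolerance = 0.03)
  expect_lt(abs(rep_$q_s), abs(rep_$q_str))
})

test_that("mesh refinement and domain extension leave the regulated charge unchanged", {
  cond <- cond_100mM()
  m <- regulation_benchmark_model()
  q1 <- net_charge(solve_sphere(m, cond))
  q_half <- net_charge(solve_sphere(m, cond, pb_control(mesh_scale = 0.5)))
  expect_equal(q_half / q1, 1, tolerance = 0.01)
  q_far <- net_charge(solve_sphere(m, cond, pb_control(domain_factor = 15)))
  expect_equal(q_far / q1, 1, tolerance = 0.005)
})

test_that("damped Picard iteration agrees with the Newton path", {
  cond <- cond_100mM(pH = 9)
  m <- sphere_model(2, 78.5, group_set(list(acid_group(2)), 1),
                    born_on = FALSE)
  fn <- solve_sphere(m, cond)
  fp <- solve_sphere(m, cond, pb_control(method = "picard"))
  expect_lt(max(abs(fn$psi - fp$psi)), 1e-4)
})

test_that("electroneutrality and the Gauss-law charge cross-check hold", {
  ## low salt keeps the screening cloud off the first exterior cell so the
  ## surface flux isolates the object charge
  cond <- solution_conditions(7, 0.001)
  m <- regulation_benchmark_model()
  f <- solve_sphere(m, cond)
  qs <- net_charge(f)
  expect_equal(ion_charge(f), -qs, tolerance = 0.01)
  isurf <- which.min(abs(f$r - m$radius))
  expect_equal(gauss_charge(f, f$r[isurf] + 1e-3), qs,
               tolerance = 0.01)
})

test_that("the constant-charge free energy scales quadratically in the linear regime", {
  cond <- solution_conditions(9, 0.001)
  f1 <- solve_sphere(sphere_model(1, 78.5,
                                  group_set(list(acid_group(3)), 0.2),
                                  born_on = FALSE), cond)
  f2 <- solve_sphere(sphere_model(1, 78.5,
                                  group_set(list(acid_group(3)), 0.4),
                                  born_on = FALSE), cond)
  expect_equal(free_energy(f2) / free_energy(f1), 4, tolerance = 0.05)
  ## flat field has zero free energy
  f0 <- solve_sphere(sphere_model(1, 78.5,
                                  group_set(list(acid_group(3)), 1e-9),
                                  born_on = FALSE), cond)
  expect_lt(abs(free_energy(f0)), 1e-8)
})

test_that("graded axes contain their anchors and respect the spacing cap", {
  ax <- graded_axis(c(0, 2, 10), c(0.5, 0.01, 0.3), h_max = 1)
  expect_true(all(abs(vapply(c(0, 2, 10), function(a) min(abs(ax - a)), 0))
                  < 1e-9))
  expect_lt(max(diff(ax)), 1 + 1e-9)
  expect_true(min(diff(ax)) >= 0.01 / 2)
})
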