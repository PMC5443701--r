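## Regulated charge, titration, dielectric inference, core-shell pKa.

test_that("regulation vanishes for a weak charge in a water-like interior", {
  cond <- cond_100mM()
  gs <- group_set(list(acid_group(4)), 0.25)
  m <- sphere_model(5.1, 78.5, gs, born_on = FALSE)
  rep_ <- regulated_charge(m, cond)
  expect_equal(rep_$eta_g, 1, tolerance = 0.01)
})

test_that("lowering the salt concentration deepens charge regulation", {
  m <- regulation_benchmark_model()
  eta_100 <- regulated_charge(m, cond_100mM())$eta_g
  eta_1 <- regulated_charge(m, solution_conditions(7, 0.001))$eta_g
  expect_lt(eta_1, eta_100)
})

test_that("eta_g and q_s increase monotonically with the interior dielectric constant", {
  cond <- cond_100mM()
  gs <- group_set(list(acid_group(4)), 12.75)
  etas <- qss <- numeric(0)
  for (ep in c(4, 20, 40, 78.5)) {
    rep_ <- regulated_charge(sphere_model(5.1, ep, gs), cond)
    etas <- c(etas, rep_$eta_g)
    qss <- c(qss, rep_$q_s)
  }
  expect_true(all(diff(etas) > 0))
  expect_true(all(diff(qss) < 0))   # more negative charge retained
})

test_that("acid-only titration curves are non-increasing and mixed curves cross zero once", {
  cond <- cond_100mM()
  gs <- group_set(list(acid_group(4)), 6)
  m <- sphere_model(2.5, 40, gs, born_on = FALSE)
  tc <- titration_curve(m, cond, seq(2, 9, by = 0.5))
  expect_true(all(diff(tc$q_s) < 1e-6))
  ## symmetric acid/base pair: pI at the midpoint pH (grid offset so the
  ## curve does not land exactly on zero at a node)
  gs2 <- group_set(list(acid_group(4), base_group(10)), c(5, 5))
  m2 <- sphere_model(2.5, 78.5, gs2, born_on = FALSE)
  tc2 <- titration_curve(m2, cond, seq(4.25, 9.75, by = 0.5))
  sg <- sign(tc2$q_s)
  crossings <- sum(sg[-1] * sg[-length(sg)] < 0)
  expect_equal(crossings, 1)
  expect_equal(isoelectric_point(tc2), 7, tolerance = 0.05)
  ## adding a basic group raises the isoelectric point
  gs3 <- group_set(list(acid_group(4), base_group(10)), c(5, 6))
  tc3 <- titration_curve(sphere_model(2.5, 78.5, gs3, born_on = FALSE),
                         cond, seq(4.25, 9.75, by = 0.5))
  expect_gt(isoelectric_point(tc3), isoelectric_point(tc2))
  ## no crossing reported as an error
  tc4 <- titration_curve(m, cond, seq(6, 9, by = 0.5))
  expect_error(isoelectric_point(tc4), "no zero crossing")
})

test_that("a regulated cylinder titration is consistent with the surface-potential closed form", {
  ## single surface group at low charge: q_s should equal the ideal value
  ## evaluated at the computed surface potential
  cond <- cond_100mM()
  gs <- group_set(list(acid_group(5)), 4)
  m <- cylinder_model(0.5, 15, surface_groups = gs)
  rep_ <- regulated_charge(m, cond)
  a_expect <- ionization_fraction(acid_group(5), cond$pH, rep_$psi_surface)
  expect_equal(rep_$q_s, -4 * a_expect, tolerance = 1e-6)
})

test_that("the interior dielectric constant is recovered from its own regulated charge", {
  cond <- cond_100mM()
  m <- regulation_benchmark_model()
  q20 <- regulated_charge(m, cond)$q_s
  ep <- infer_interior_dielectric(m, cond, q20)
  expect_equal(ep, 20, tolerance = 0.01 * 20)
  ## a charge beyond the attainable range errors with the bracketing values
  expect_error(infer_interior_dielectric(m, cond, -14), "not attainable")
})

test_that("core-shell pKa recovers the nominal value in a bulk-like environment", {
  cond <- cond_100mM()
  glu <- ionizable_group(4.3, -1, label = "Glu")
  cs <- core_shell_model(2.2, 0.6, 78.5, 78.5, glu, shell_charge = 0)
  pk <- core_shell_pka(cs, cond, seq(2, 7, by = 0.25),
                       self_interaction = "excluded")
  expect_equal(pk$pKa, 4.3, tolerance = 0.02)
  ## with the smeared self-interaction included the shift is small and
  ## positive for an acid
  pk2 <- core_shell_pka(cs, cond, seq(2, 7, by = 0.25),
                        self_interaction = "included")
  expect_gt(pk2$pKa, 4.3)
  expect_lt(pk2$pKa, 4.8)
})

test_that("core-shell pKa shifts span several units over the buried-dielectric range", {
  cond <- cond_100mM()
  glu <- ionizable_group(4.3, -1, label = "Glu")
  pks <- vapply(c(10, 25), function(ec) {
    cs <- core_shell_model(2.2, 0.6, ec, 40, glu, shell_charge = 8)
    core_shell_pka(cs, cond)$pKa
  }, 0)
  ## low-dielectric burial drives large upward shifts for an acid
  expect_true(all(diff(pks) < 0))
  expect_gt(pks[1], 6.5)            # eps_c = 10: strongly shifted
  expect_lt(pks[2], 5.5)            # eps_c = 25: mildly shifted
  expect_gt(pks[1] - pks[2], 2.5)
  ## shrinking the core strengthens the self-interaction shift
  cs5 <- core_shell_model(2.2, 0.5, 15, 40, glu, shell_charge = 8)
  cs6 <- core_shell_model(2.2, 0.6, 15, 40, glu, shell_charge = 8)
  dpk <- core_shell_pka(cs5, cond)$pKa - core_shell_pka(cs6, cond)$pKa
  expect_gt(dpk, 0.03)
  expect_lt(dpk, 0.25)
})

test_that("half-ionization outside the grid is reported, not extrapolated", {
  cond <- cond_100mM()
  glu <- ionizable_group(4.3, -1, label = "Glu")
  cs <- core_shell_model(2.2, 0.6, 10, 40, glu, shell_charge = 8)
  expect_error(core_shell_pka(cs, cond, seq(1, 3, by = 0.5)),
               "not bracketed")
})
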