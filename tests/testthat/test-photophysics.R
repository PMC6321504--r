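test_that("isotropic quadruple matches the closed-form photoselection limits", {
  q0 <- isotropic_quadruple(collinear)
  expect_equal(unname(q0[["I_pp"]] / q0[["I_pt"]]), 3)          # 3:1 ratio
  expect_equal(polarization_ratios(q0)$P_par, 0.5)
  expect_equal(q0[["I_pp"]], q0[["I_tt"]])
  expect_equal(q0[["I_pt"]], q0[["I_tp"]])

  qm <- isotropic_quadruple(probe_geometry("magic", gamma = 54.7356))
  pr <- polarization_ratios(qm)
  expect_lt(abs(pr$P_par), 1e-6)
  expect_lt(abs(pr$P_perp), 1e-6)
})

test_that("isotropic quadruple agrees with the rigid dipole-pair Monte Carlo", {
  withr::local_seed(101)
  mc <- mc_isotropic_quadruple(gamma = 20, n = 1e7)
  q <- as.numeric(isotropic_quadruple(aedans))
  expect_true(all(abs(q - mc$mean) <= 3 * mc$se))
  expect_true(all(abs(q - mc$mean) / mc$mean <= 1e-3))
})

test_that("isotropic closed form reproduces the fundamental anisotropy", {
  for (g in c(0, 10, 20, 35, 54.7356, 70, 90)) {
    q <- isotropic_quadruple(probe_geometry("p", gamma = g))
    r0 <- (q[["I_pp"]] - q[["I_pt"]]) / (q[["I_pp"]] + 2 * q[["I_pt"]])
    expect_lt(abs(r0 - (3 * cos(g * pi / 180)^2 - 1) / 5), 1e-12)
  }
})

test_that("ordered quadruple handles the axial and magic-angle limits", {
  # all dipoles along the fiber axis: only the par/par component survives
  st0 <- orientation_state(phi_e = 0, n = 0, theta_half = 0, phi_a = 0)
  q0 <- ordered_quadruple(st0, collinear)
  expect_gt(q0[["I_pp"]], 0)
  expect_equal(unname(q0[["I_pt"]] + q0[["I_tt"]] + q0[["I_tp"]]), 0)
  expect_equal(polarization_ratios(c(q0[1], q0[2], 1e-30, 1e-30))$P_par, 1)

  # cone at the magic angle: both ratios vanish and are equal
  stm <- orientation_state(phi_e = 54.7356, n = 0, theta_half = 0,
                           phi_a = 54.7356)
  pr <- polarization_ratios(ordered_quadruple(stm, collinear))
  expect_lt(abs(pr$P_par - pr$P_perp), 1e-6)
  expect_lt(abs(pr$P_par), 1e-5)
})

test_that("ordered quadruple agrees with Monte Carlo within 3 standard errors", {
  withr::local_seed(202)
  cases <- list(
    list(phi_a = 31.2, phi_e = 51.2, th = 25, wobble = "uniform"),
    list(phi_a = 31.2, phi_e = 51.2, th = 25, wobble = "solid_angle"),
    list(phi_a = 60, phi_e = 45, th = 40, wobble = "uniform"),
    list(phi_a = 10, phi_e = 10, th = 0, wobble = "uniform"))
  for (cs in cases) {
    st <- orientation_state(phi_e = cs$phi_e, n = 0, theta_half = cs$th,
                            phi_a = cs$phi_a)
    q <- as.numeric(ordered_quadruple(st, probe_geometry("p", gamma = 20),
                                      quadrature_settings(wobble = cs$wobble)))
    mc <- mc_ordered_quadruple(cs$phi_a, cs$phi_e, cs$th, n = 1e6,
                               wobble = cs$wobble)
    expect_true(all(abs(q - mc$mean) <= 3 * mc$se + 1e-12),
                label = sprintf("quadrature vs MC (%s, theta %g)",
                                cs$wobble, cs$th))
  }
  # canonical weak-binding geometry to 1e-3 relative at large draw count
  st <- orientation_state(phi_e = 51.2, n = 0, theta_half = 25, phi_a = 31.2)
  q <- as.numeric(ordered_quadruple(st, probe_geometry("p", gamma = 20)))
  mc <- mc_ordered_quadruple(31.2, 51.2, 25, n = 1e7)
  expect_true(all(abs(q - mc$mean) / mc$mean <= 1e-3))
})

test_that("locked-azimuth variant matches its own Monte Carlo and differs from independent", {
  withr::local_seed(303)
  st <- orientation_state(phi_e = 51.2, n = 0, theta_half = 25, phi_a = 31.2)
  qk <- as.numeric(ordered_quadruple(st, aedans,
                                     quadrature_settings(azimuth = "locked")))
  mc <- mc_ordered_quadruple(31.2, 51.2, 25, gamma = 20, n = 1e6,
                             azimuth = "locked")
  expect_true(all(abs(qk - mc$mean) <= 3 * mc$se + 1e-12))
  qi <- as.numeric(ordered_quadruple(st, aedans))
  expect_gt(max(abs(qk - qi)), 1e-3)
})

test_that("perp/par symmetry holds for collinear dipoles", {
  for (phi in c(15, 40, 70)) {
    for (th in c(0, 20, 45)) {
      st <- orientation_state(phi_e = phi, n = 0, theta_half = th, phi_a = phi)
      q <- ordered_quadruple(st, collinear)
      expect_lt(abs(q[["I_pt"]] - q[["I_tp"]]) / max(q[["I_pt"]], 1e-12), 1e-6)
      qk <- ordered_quadruple(st, collinear,
                              quadrature_settings(azimuth = "locked"))
      expect_lt(abs(qk[["I_pt"]] - qk[["I_tp"]]) / max(qk[["I_pt"]], 1e-12), 1e-6)
    }
  }
})

test_that("wobble depolarizes: P_par decreases with theta_half below the magic angle", {
  for (phi in c(20, 40, 50)) {
    th_grid <- seq(0, 60, by = 5)
    ppar <- vapply(th_grid, function(th) {
      st <- orientation_state(phi_e = phi, n = 0, theta_half = th, phi_a = phi)
      polarization_ratios(ordered_quadruple(st, collinear))$P_par
    }, numeric(1))
    expect_true(all(diff(ppar) < 0), label = sprintf("phi = %g", phi))
  }
})

test_that("closed-form wobble moments agree with Gauss-Legendre quadrature", {
  for (wob in c("uniform", "solid_angle")) {
    qs <- quadrature_settings(wobble = wob)
    for (th in c(5, 25, 45, 80) * pi / 180) {
      expect_equal(fiberpol:::wobble_moments(th, qs),
                   fiberpol:::wobble_moments_quadrature(th, qs),
                   tolerance = 1e-10)
    }
  }
})

test_that("quadrature convergence failure is reported with the achieved tolerance", {
  qs <- quadrature_settings(n_theta = 8L, rel_tol = 1e-14)
  expect_error(fiberpol:::wobble_moments_quadrature(1.2, qs),
               "non-convergent.*achieved")
})

test_that("mixture model is linear in the disordered fraction", {
  st_ord <- orientation_state(phi_e = 51.2, n = 0, theta_half = 25, gamma = 20)
  ord <- as.numeric(ordered_quadruple(st_ord, aedans))
  iso <- as.numeric(isotropic_quadruple(aedans))
  expect_equal(as.numeric(model_quadruple(st_ord, aedans)), ord)
  st_iso <- orientation_state(phi_e = 51.2, n = 1, theta_half = 25, gamma = 20)
  expect_equal(as.numeric(model_quadruple(st_iso, aedans)), iso)
  st_half <- orientation_state(phi_e = 51.2, n = 0.5, theta_half = 25, gamma = 20)
  expect_equal(as.numeric(model_quadruple(st_half, aedans)), (ord + iso) / 2)
})

test_that("polarization ratios evaluate the defining formulas and are scale invariant", {
  expect_equal(polarization_ratios(c(3, 1, 3, 1)), list(P_par = 0.5, P_perp = 0.5))
  expect_equal(polarization_ratios(c(1, 1, 1, 1)), list(P_par = 0, P_perp = 0))
  expect_equal(polarization_ratios(c(2, 1, 4, 2)),
               list(P_par = 1 / 3, P_perp = 1 / 3))
  q <- c(0.22, 0.133, 0.126, 0.068)
  for (c_scale in c(1e-3, 7, 1e4))
    expect_equal(polarization_ratios(q * c_scale), polarization_ratios(q))
  expect_error(polarization_ratios(c(0, 0, 1, 1)), "zero denominator")
})

test_that("infeasible dipole geometry is rejected with the violated constraint", {
  expect_error(
    ordered_quadruple(orientation_state(phi_e = 80, n = 0, theta_half = 0,
                                        phi_a = 10), aedans),
    "phi_a - phi_e")
  expect_error(orientation_state(phi_e = 5, n = 0, theta_half = 0,
                                 phi_a = 5, gamma = 20),
               "phi_a \\+ phi_e")
})

test_that("magic-angle solve finds 54.74 degrees and a true crossing", {
  root <- magic_angle_solve(collinear, theta_half = 0)
  expect_equal(root, 54.74, tolerance = 0.01 / 54.74)
  st <- orientation_state(phi_e = root, n = 0, theta_half = 0, phi_a = root)
  pr <- polarization_ratios(ordered_quadruple(st, collinear))
  expect_lt(abs(pr$P_par - pr$P_perp), 1e-6)
})

test_that("magic-angle solve matches a dense grid scan for a real probe angle", {
  pg <- probe_geometry("g20", gamma = 20)
  root <- magic_angle_solve(pg, theta_half = 0)
  grid <- seq(10.1, 89.9, by = 0.01)
  dd <- vapply(grid, function(phi) {
    st <- orientation_state(phi_e = phi, n = 0, theta_half = 0, phi_a = phi)
    pr <- polarization_ratios(ordered_quadruple(st, pg))
    pr$P_par - pr$P_perp
  }, numeric(1))
  cross <- grid[which(diff(sign(dd)) != 0)[1]]
  expect_equal(root, cross, tolerance = 0.02 / cross)
})
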