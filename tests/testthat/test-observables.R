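test_that("averaged bond length respects symmetry and translation", {
  m1 <- particle_mass("custom", mass = 1)
  g <- grid_spec(-2.5, 2.5, 601)
  cv <- make_harmonic(k_unit, 0, r0 = 1.5, grid = g)
  sp <- solve_states(cv, m1, g)
  expect_equal(expectation_bond_length(sp, 0), 1.5, tolerance = 1e-9)

  g2 <- grid_spec(-2.3, 2.7, 601)
  cv2 <- make_harmonic(k_unit, q_min = 0.2, r0 = 1.5, grid = g2)
  sp2 <- solve_states(cv2, m1, g2)
  expect_equal(expectation_bond_length(sp2, 0), 1.7, tolerance = 1e-8)

  expect_error(expectation_bond_length(sp, 7),
               class = "vibhb_parameter_error")
})

test_that("morse ground state elongates and matches a quadrature oracle", {
  m1 <- particle_mass("custom", mass = 1)
  g <- grid_spec(-1.2, 4, 901)
  cv <- make_morse(40, 1.2, q_min = 0, r0 = 1.0, grid = g)
  sp <- solve_states(cv, m1, g)
  r_mean <- expectation_bond_length(sp, 0)
  expect_gt(r_mean, 1.0) # anharmonic elongation beyond the minimum
  q <- grid_points(sp$grid)
  oracle <- 1.0 + trapz(q, q * sp$wavefunctions[, 1]^2) /
    trapz(q, sp$wavefunctions[, 1]^2)
  expect_equal(r_mean, oracle, tolerance = 1e-6)
})

test_that("boltzmann weights: limits, published-level ratio, gauge invariance", {
  expect_equal(boltzmann_weights(2.02, 300), 1)
  expect_equal(boltzmann_weights(c(1, 2, 3), 1e9), rep(1 / 3, 3),
               tolerance = 1e-6)

  # proton levels at the equilibrium geometry: first-excited population
  eps <- c(2.02, 5.46, 10.14)
  w <- boltzmann_weights(eps, 300)
  expect_equal(w[2] / w[1], exp(-(5.46 - 2.02) / (oracle_kB * 300)),
               tolerance = 1e-5)
  expect_lt(w[2] / w[1], 0.03)

  expect_equal(boltzmann_weights(eps + 7.5, 300),
               boltzmann_weights(eps, 300), tolerance = 1e-12)
  expect_error(boltzmann_weights(eps, -1),
               class = "vibhb_parameter_error")
})

test_that("thermal averaging reproduces the published room-temperature lengths", {
  # equilibrium-geometry tables, printed to 2 decimals
  r_h <- thermal_average(c(1.17, 1.23, 1.21), c(2.02, 5.46, 10.14), 300)
  r_d <- thermal_average(c(1.15, 1.24, 1.22), c(1.47, 3.73, 6.52), 300)
  expect_equal(round(r_h, 2), 1.17)
  expect_equal(round(r_d, 2), 1.15)

  expect_equal(thermal_average(rep(3.3, 4), c(1, 2, 3, 4), 77), 3.3)
  expect_error(thermal_average(1:3, 1:2, 300),
               class = "vibhb_parameter_error")
})

test_that("thermal average interpolates between ground value and uniform mean", {
  vals <- c(1.1, 1.4)
  eps <- c(1, 2)
  expect_equal(thermal_average(vals, eps, 1e-3), 1.1)
  temps <- 10^seq(1, 6, length.out = 12)
  rt <- sapply(temps, function(tt) thermal_average(vals, eps, tt))
  expect_true(all(diff(rt) > 0))
  expect_true(all(rt >= 1.1 & rt <= mean(vals) + 1e-9))
})

test_that("excitation gaps match the printed tables", {
  # equilibrium proton: 5.46 - 2.02
  expect_equal(excitation_gaps(c(2.02, 5.46, 10.14))[1], 3.44)
  # crystal deuteron: 2.63 - 1.67
  expect_equal(excitation_gaps(c(1.67, 2.63, 4.77))[1], 0.96)
  gaps <- excitation_gaps(c(1.67, 2.63, 4.77))
  expect_true(all(gaps > 0) && all(diff(gaps) > 0))
  expect_error(excitation_gaps(2.02), class = "vibhb_parameter_error")
})

test_that("stationary-point analysis recovers the symmetric quartic barrier", {
  b <- 0.25
  a <- 120
  q <- seq(-0.7, 0.7, length.out = 401)
  cv <- potential_curve(q, a * (q^2 - b^2)^2, r0 = 1)
  ba <- barrier_analysis(cv)
  expect_equal(attr(ba, "classification"), "double-well")
  expect_equal(attr(ba, "barrier_height"), a * b^4, tolerance = 1e-8)
  expect_equal(attr(ba, "barrier_q"), 0, tolerance = 1e-8)
  expect_equal(sort(ba$q[ba$type == "minimum"]), c(-b, b),
               tolerance = 1e-6)
})

test_that("monotone curves without interior minima are degenerate", {
  q <- seq(0, 1, length.out = 21)
  cv <- potential_curve(q, 5 * q, r0 = 1)
  expect_error(barrier_analysis(cv),
               class = "vibhb_degenerate_curve_error")
})

test_that("LBHB classification covers all three regimes", {
  eq <- make_pyp_equilibrium_fixture()
  cls <- lbhb_classify(eq)
  expect_equal(cls$classification, "no-barrier (single-well)")

  g <- grid_spec(-0.7, 0.8, 601)
  deep <- make_double_well(-0.3, 0, 0.3, 100, 0, r0 = 1.2, grid = g)
  sp_deep <- suppressWarnings(solve_states(deep, "H", g))
  cls_deep <- lbhb_classify(deep, sp_deep)
  expect_equal(cls_deep$classification, "barrier-localized")
  expect_gt(cls_deep$zpe_barrier_gap, 0)

  cr <- make_pyp_crystal_fixture()
  sp_h <- solve_quiet(cr, "H")
  cls_cr <- lbhb_classify(cr, sp_h)
  expect_equal(cls_cr$classification, "ZPE-dominated (LBHB-like)")
})

test_that("thermal report satisfies its weight and bracketing invariants", {
  cr <- make_pyp_crystal_fixture()
  sp <- solve_quiet(cr, "D")
  tr <- thermal_report(sp, cr, 300)
  expect_equal(sum(tr$weight), 1, tolerance = 1e-12)
  expect_true(all(diff(tr$weight) <= 0))
  r_t <- attr(tr, "r_t")
  expect_gte(r_t, min(tr$mean_r))
  expect_lte(r_t, max(tr$mean_r))
})

test_that("isotope report: null case, harmonic scaling, crystal ordering", {
  cr <- make_pyp_crystal_fixture()
  g <- grid_spec(-0.45, 0.75, 601)
  sp_h <- solve_quiet(cr, "H", g)
  sp_d <- solve_quiet(cr, "D", g)

  # identical masses give exactly zero differences
  null_rep <- isotope_report(sp_h, sp_h, cr, 300)
  expect_identical(attr(null_rep, "delta_mean_r_ground"), 0)

  # harmonic zero-point energies scale as sqrt(m_H / m_D)
  gh <- grid_spec(-2.5, 2.5, 601)
  hcv <- make_harmonic(k_unit, 0, 1.0, gh)
  zh <- zero_point_energy(solve_states(hcv, "H", gh))
  zd <- zero_point_energy(solve_states(hcv, "D", gh))
  expect_equal(zd / zh, sqrt(mass_H / mass_D), tolerance = 1e-4)

  # the proton spreads past the barrier more than the deuteron
  rep_cr <- isotope_report(sp_h, sp_d, cr, 300)
  expect_gt(attr(rep_cr, "delta_mean_r_ground"), 0)
  expect_true(all(rep_cr$first_gap > 0))
  expect_true(all(is.finite(unlist(rep_cr[-1]))))

  sp_other <- solve_quiet(cr, "D", grid_spec(-0.45, 0.75, 501))
  expect_error(isotope_report(sp_h, sp_other, cr),
               class = "vibhb_parameter_error")
})
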