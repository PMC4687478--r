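test_that("harmonic generator matches its closed form", {
  g <- grid_spec(-2, 2, 401)
  cv <- make_harmonic(force_constant = 2, q_min = 0, r0 = 1, grid = g)
  # symmetry about the minimum and E = k/2 q^2 spot value
  expect_equal(cv$energy, rev(cv$energy))
  expect_equal(cv$energy[which.min(abs(cv$q - 1))], 1, tolerance = 1e-12)
  expect_equal(min(cv$energy), 0)

  off <- make_harmonic(5, q_min = 0.3, r0 = 1, grid = g)
  expect_equal(off$q[which.min(off$energy)], 0.3, tolerance = 1e-9)

  expect_error(make_harmonic(-1, 0, 1, g),
               class = "vibhb_parameter_error")
  expect_error(make_harmonic(1, q_min = 5, 1, g),
               class = "vibhb_parameter_error")
})

test_that("morse generator has zero minimum and dissociation plateau", {
  g <- grid_spec(-1, 6, 701)
  cv <- make_morse(d_e = 5, a = 2, q_min = 0, r0 = 1, grid = g)
  expect_equal(cv$energy[which.min(abs(cv$q))], 0, tolerance = 1e-12)
  right <- cv$energy[cv$q > 0]
  expect_true(all(diff(right) > 0))
  expect_true(all(right < 5))
  expect_equal(cv$energy[length(cv$energy)], 5, tolerance = 1e-4)
  expect_error(make_morse(-1, 1, 0, 1, g),
               class = "vibhb_parameter_error")
  expect_error(make_morse(1, -1, 0, 1, g),
               class = "vibhb_parameter_error")
})

test_that("symmetric double well reduces to the closed-form quartic", {
  b <- 0.2
  h <- 3
  g <- grid_spec(-0.6, 0.6, 801)
  cv <- make_double_well(-b, 0, b, h, 0, r0 = 1, grid = g)
  a <- h / b^4 # a * b^4 = barrier height
  expect_equal(cv$energy, a * (cv$q^2 - b^2)^2, tolerance = 1e-10)
  ba <- barrier_analysis(cv)
  expect_equal(attr(ba, "barrier_height"), h, tolerance = 1e-8)
  expect_equal(attr(ba, "barrier_q"), 0, tolerance = 1e-8)
})

test_that("asymmetric double well honours its constraint set", {
  g <- grid_spec(-0.5, 0.8, 301)
  cv <- make_double_well(-0.15, 0.1, 0.4, 2.5, 0.8, r0 = 1.2,
                         grid = g)
  cf <- attr(cv, "coefficients")
  evalp <- function(q) sum(cf * q^(seq_along(cf) - 1))
  expect_equal(evalp(-0.15), 0, tolerance = 1e-9)
  expect_equal(evalp(0.1), 2.5, tolerance = 1e-9)
  expect_equal(evalp(0.4), 0.8, tolerance = 1e-9)

  # asymmetry 0 echoes equal well depths
  cv0 <- make_double_well(-0.15, 0.1, 0.4, 2.5, 0, r0 = 1.2, grid = g)
  cf0 <- attr(cv0, "coefficients")
  expect_equal(sum(cf0 * (-0.15)^(seq_along(cf0) - 1)),
               sum(cf0 * 0.4^(seq_along(cf0) - 1)),
               tolerance = 1e-9)

  expect_error(make_double_well(0.1, -0.1, 0.4, 2, 0, 1, g),
               class = "vibhb_parameter_error")
  expect_error(make_double_well(-0.15, 0.1, 0.4, 1, 1.5, 1, g),
               class = "vibhb_parameter_error")
  # feasible positions but stationary energies too asymmetric
  g2 <- grid_spec(-0.5, 0.6, 201)
  expect_error(make_double_well(-0.2, -0.1, 0.2, 3, 2.9, 1, g2),
               class = "vibhb_construction_error")
})

test_that("random double wells satisfy curve invariants and round-trip their constraints", {
  set.seed(421)
  for (i in 1:12) {
    m1 <- runif(1, -0.3, -0.1)
    b <- m1 + runif(1, 0.15, 0.3)
    m2 <- b + runif(1, 0.15, 0.3)
    h <- runif(1, 1, 8)
    asym <- runif(1, 0, 0.7 * h)
    g <- grid_spec(m1 - 0.3, m2 + 0.4, 401)
    cv <- make_double_well(m1, b, m2, h, asym, r0 = 1.2, grid = g)
    # curve invariants
    expect_true(all(diff(cv$q) > 0))
    expect_true(all(is.finite(cv$energy)))
    expect_gte(min(cv$energy), -1e-8)
    # stationary analysis recovers the generator's constraints
    ba <- barrier_analysis(cv)
    expect_equal(attr(ba, "classification"), "double-well")
    expect_equal(attr(ba, "barrier_height"), h, tolerance = 1e-6)
    expect_equal(attr(ba, "barrier_q"), b, tolerance = 1e-5)
    expect_equal(attr(ba, "e_min"), 0, tolerance = 1e-6)
  }
})

test_that("equilibrium fixture is a single anharmonic well at R = 1.08", {
  cv <- make_pyp_equilibrium_fixture()
  expect_equal(curve_r0(cv), 1.08)
  ba <- barrier_analysis(cv)
  expect_equal(attr(ba, "classification"), "single-well")
  expect_equal(sum(ba$type == "minimum"), 1)
  expect_equal(sum(ba$type == "maximum"), 0)
  expect_equal(attr(ba, "q_min"), 0, tolerance = 1e-6)
  # strictly increasing outer branch, stiffer inner wall
  outer_branch <- cv$energy[cv$q > 0]
  expect_true(all(diff(outer_branch) > 0))
  inner <- cv$energy[which.min(abs(cv$q + 0.3))]
  outer <- cv$energy[which.min(abs(cv$q - 0.3))]
  expect_gt(inner, outer)
})

test_that("crystal fixture carries the printed calibration", {
  cv <- make_pyp_crystal_fixture()
  expect_equal(curve_r0(cv), 1.21)
  ba <- barrier_analysis(cv)
  expect_equal(attr(ba, "classification"), "double-well")
  expect_equal(attr(ba, "barrier_height"), 2.36, tolerance = 1e-4)
  expect_equal(attr(ba, "barrier_q"), 0.10, tolerance = 1e-4)
  # bond length at the global minimum: R0 - 0.15 = 1.06
  expect_equal(attr(ba, "r_min"), 1.06, tolerance = 1e-4)
  # barrier top sits at the printed O-H length 1.31
  expect_equal(bond_length(cv, attr(ba, "barrier_q")), 1.31,
               tolerance = 1e-4)
})
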