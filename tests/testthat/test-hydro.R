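test_that("additive partial specific volumes reproduce the complex values", {
  # one tetramer (4 x 21.95 kDa, 0.711 ml/g) + one or two RecO (27.4, 0.734)
  expect_equal(vbar_additive(c(4, 1), c(21.95, 27.4), c(0.711, 0.734)),
               0.716, tolerance = 1e-3)
  expect_equal(vbar_additive(c(4, 2), c(21.95, 27.4), c(0.711, 0.734)),
               0.720, tolerance = 1e-3)
  # single component is the identity
  expect_identical(vbar_additive(3, 50, 0.73), 0.73)
})

test_that("vbar_additive is invariant to reordering and mole rescaling", {
  m <- c(4, 1); M <- c(21.95, 27.4); v <- c(0.711, 0.734)
  base <- vbar_additive(m, M, v)
  expect_equal(vbar_additive(rev(m), rev(M), rev(v)), base)
  expect_equal(vbar_additive(7 * m, M, v), base)
  # bounded by the component range
  expect_gt(base, min(v))
  expect_lt(base, max(v))
  expect_error(vbar_additive(numeric(0), numeric(0), numeric(0)), "empty")
  expect_error(vbar_additive(1, 10, 1.2), "vbar")
})

test_that("total molar mass reproduces the expected complex masses", {
  expect_equal(total_molar_mass(c(4, 2), c(21.95, 27.4)), 142.6)
  expect_equal(total_molar_mass(c(4, 1), c(21.95, 27.4)), 115.2)
  expect_equal(total_molar_mass(2, 21.95), 43.9)
  expect_error(total_molar_mass(numeric(0), numeric(0)), "empty")
})

test_that("buoyant factor is M(1 - vbar rho), linear in M, zero at neutrality", {
  b <- buffer_state(density = 0.99823, viscosity = 1.002)
  expect_equal(buoyant_factor(27.4, 0.734, b), 27.4 * (1 - 0.734 * 0.99823))
  b_neutral <- buffer_state(density = 1 / 0.734, viscosity = 1)
  expect_equal(buoyant_factor(27.4, 0.734, b_neutral), 0)
  expect_equal(buoyant_factor(2 * 27.4, 0.734, b), 2 * buoyant_factor(27.4, 0.734, b))
  # strictly decreasing in density
  b_hi <- buffer_state(density = 1.1, viscosity = 1)
  expect_lt(buoyant_factor(27.4, 0.734, b_hi), buoyant_factor(27.4, 0.734, b))
})

test_that("diffusion coefficient follows the Svedberg relation", {
  b <- buffer_state(density = 1.06, viscosity = 2, temperature = 298.15)
  # hand evaluation: D = s R T / M(1 - vbar rho), SI, then to cm^2/s
  mb <- 27.4 * (1 - 0.734 * 1.06)            # kg/mol
  d_exp <- 0.87e-13 * 8.314462618 * 298.15 / mb * 1e4
  expect_equal(diffusion_from_s(0.87, 27.4, 0.734, b), d_exp, tolerance = 1e-12)
  expect_equal(diffusion_from_s(0, 27.4, 0.734, b), 0)
  # halving M doubles D at fixed s
  expect_equal(diffusion_from_s(0.87, 13.7, 0.734, b),
               2 * diffusion_from_s(0.87, 27.4, 0.734, b))
  b_neutral <- buffer_state(density = 1 / 0.734, viscosity = 1)
  expect_error(diffusion_from_s(1, 27.4, 0.734, b_neutral), "buoyancy")
})

test_that("s20,w correction: identity in reference water, linear in viscosity,
           exact round trip", {
  expect_equal(s20w_correct(0.87, water_20C(), 0.734), 0.87)
  b2 <- buffer_state(density = 0.99823, viscosity = 2.004)
  expect_equal(s20w_correct(1, b2, 0.7), 2, tolerance = 1e-12)
  b <- btp_buffer()
  s <- s20w_correct(0.87, b, 0.734)
  expect_equal(s20w_correct(s, b, 0.734, inverse = TRUE), 0.87,
               tolerance = 1e-12)
  # RecO: extrapolated 0.87 S in the glycerol buffer corrects to near 2.32 S
  expect_equal(s, 2.32, tolerance = 0.1)
})

test_that("glycerol-water property table matches water and is monotone", {
  w <- glycerol_buffer_properties(0, 293.15)
  expect_equal(w$density, 0.99823, tolerance = 1e-4)
  expect_equal(w$viscosity, 1.002, tolerance = 5e-3)
  r <- vapply(c(0, 10, 25, 40), function(g)
    glycerol_buffer_properties(g, 298.15)$density, 0)
  expect_true(all(diff(r) > 0))
  e <- vapply(c(0, 10, 25, 40), function(g)
    glycerol_buffer_properties(g, 298.15)$viscosity, 0)
  expect_true(all(diff(e) > 0))
  # frozen regression values for the working buffer composition
  p25 <- glycerol_buffer_properties(25, 298.15)
  expect_equal(p25$density, 1.06958, tolerance = 1e-5)
  expect_equal(p25$viscosity, 2.0964, tolerance = 1e-4)
  expect_error(glycerol_buffer_properties(60, 298.15), "range")
  expect_error(glycerol_buffer_properties(25, 350), "range")
  # salt density increment is linear
  expect_equal(glycerol_buffer_properties(25, 298.15, salt_molar = 0.2)$density -
                 p25$density, 0.041 * 0.2)
})

test_that("species and buffer constructors enforce their invariants", {
  comp <- data.frame(component = c("RecR", "RecO"), copies = c(4, 2),
                     molar_mass = c(21.95, 27.4), vbar = c(0.711, 0.734))
  sp <- species("RecR4O2", composition = comp, extinction = 5.22e5)
  expect_equal(sp$molar_mass, 142.6)
  expect_equal(sp$vbar, 0.720, tolerance = 1e-3)
  expect_error(species("bad", molar_mass = 100, vbar = 0.72,
                       composition = comp), "disagrees")
  expect_error(species("bad", molar_mass = -1, vbar = 0.7), "positive")
  expect_error(buffer_state(1, 1, temperature = 500))
  expect_error(buffer_state(-1, 1))
})
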