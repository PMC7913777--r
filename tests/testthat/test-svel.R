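buf <- btp_buffer()

test_that("equilibrium composition matches the bisection oracle on a grid", {
  net <- scheme_network("noP15")
  for (o_um in c(0.1, 0.5, 1.5, 5, 20)) for (r_um in c(0.1, 1, 3, 9, 20)) {
    eq <- equilibrium_composition(o_um * 1e-6, r_um * 1e-6, net)
    oracle <- equilibrium_bisect(o_um * 1e-6, r_um * 1e-6, net$K)
    expect_equal(unname(eq), unname(oracle),
                 tolerance = 1e-8)
  }
})

test_that("equilibrium composition conserves and degenerates correctly", {
  # no association at all: only free O and free dimer
  net0 <- reaction_network(L_obs = 0, K2 = 0, K3 = 0, K4 = 0)
  eq0 <- equilibrium_composition(1e-6, 4e-6, net0)
  expect_equal(eq0[["O"]], 1e-6)
  expect_equal(eq0[["R2"]], 2e-6)
  expect_equal(sum(eq0[c("R4", "R2O", "R4O", "R4O2")]), 0)
  # conservation laws hold by construction at a hard case
  net <- scheme_network("plusP15")
  eq <- equilibrium_composition(1.5e-6, 9e-6, net)
  expect_equal(eq[["O"]] + eq[["R2O"]] + eq[["R4O"]] + 2 * eq[["R4O2"]],
               1.5e-6, tolerance = 1e-10)
  expect_equal(2 * eq[["R2"]] + 2 * eq[["R2O"]] + 4 * eq[["R4"]] +
                 4 * eq[["R4O"]] + 4 * eq[["R4O2"]], 9e-6, tolerance = 1e-10)
  # strong RecO binding drives nearly all RecO into tetramer complexes
  eqn <- equilibrium_composition(1.5e-6, 9e-6, scheme_network("noP15"))
  frac_in_r4 <- (eqn[["R4O"]] + 2 * eqn[["R4O2"]]) / 1.5e-6
  expect_gt(frac_in_r4, 0.9)
})

test_that("reaction fluxes vanish at equilibrium and conserve totals", {
  net <- scheme_network("noP15")
  eq <- equilibrium_composition(1.5e-6, 9e-6, net)
  fl <- reaction_fluxes(eq, net)
  scale <- max(net$k_on * c(eq["R2"]^2, eq["O"] * eq["R2"],
                            eq["O"] * eq["R4"], eq["O"] * eq["R4O"]))
  expect_lt(max(abs(fl)), 1e-12 * scale)
  # any state conserves the two monomer totals
  cc <- c(1e-6, 2e-6, 5e-7, 1e-8, 2e-7, 3e-7)
  fl2 <- reaction_fluxes(cc, net)
  expect_lt(abs(sum(fl2 * c(1, 0, 0, 1, 1, 2))), 1e-18)
  expect_lt(abs(sum(fl2 * c(0, 2, 4, 2, 4, 4))), 1e-18)
  # K3 = 0 with R4O present: net decay of R4O
  net3 <- reaction_network(L_obs = 2.16e5, K2 = 10, K3 = 0, K4 = 4e8)
  fl3 <- reaction_fluxes(c(0, 1e-6, 1e-7, 0, 5e-7, 0), net3)
  expect_lt(unname(fl3[5]), 0)
  # single forward step from pure reactants: flux = k_on [A][B]
  net1 <- reaction_network(L_obs = 0, K2 = 0, K3 = 5e5, K4 = 0,
                           k_off = 0.01)
  fl1 <- reaction_fluxes(c(1e-6, 0, 2e-6, 0, 0, 0), net1)
  expect_equal(unname(fl1[5]), 5e5 * 0.01 * 1e-6 * 2e-6, tolerance = 1e-12)
})

test_that("diffusion-free transport tracks the analytic boundary", {
  g <- cell_geometry(n_points = 400)
  om <- g$rotor_speed * 2 * pi / 60
  tt <- c(900, 2400)
  s0 <- 2.5
  sim <- simulate_lamm_single(s0, 0, g, tt, loading = 1, dt = 2)
  dr <- diff(sim$radii[1:2])
  for (k in seq_along(tt)) {
    plateau_true <- exp(-2 * s0 * 1e-13 * om^2 * tt[k])
    rb_true <- g$meniscus * exp(s0 * 1e-13 * om^2 * tt[k])
    prof <- sim$profiles[k, ]
    i <- which(prof > plateau_true / 2)[1]
    rb_num <- sim$radii[i - 1] +
      (plateau_true / 2 - prof[i - 1]) / (prof[i] - prof[i - 1]) * dr
    expect_equal(rb_num, rb_true, tolerance = 0.01)
    # radial-dilution plateau
    mid <- prof[sim$radii > rb_true + 0.05 & sim$radii < 7.0]
    expect_equal(mean(mid), plateau_true, tolerance = 0.01)
  }
})

test_that("reacting simulation conserves monomer totals and stays put at
           zero rotor speed", {
  net <- scheme_network("noP15")
  g <- cell_geometry(n_points = 200)
  sv <- simulate_lamm(net, c(O = 1.5e-6, R = 6e-6), g,
                      times = seq(300, 1800, 300), buf, dt = 2)
  expect_lt(sv$drift, 1e-3)
  g0 <- cell_geometry(rotor_speed = 0, n_points = 120)
  sv0 <- simulate_lamm(net, c(O = 1.5e-6, R = 6e-6), g0,
                       times = c(300, 900), buf, dt = 5)
  expect_lt(max(abs(sv0$absorbance[2, ] - sv0$absorbance[1, ])), 1e-10)
})

test_that("fast reverse rates approach the instantaneous-equilibrium limit", {
  g <- cell_geometry(n_points = 150)
  tt <- seq(300, 3000, 300)
  run <- function(koff) {
    net <- reaction_network(L_obs = 2.16e5, K2 = 10, K3 = 5e5, K4 = 4e8,
                            k_off = koff)
    transport_sw(simulate_lamm(net, c(O = 1.5e-6, R = 9e-6), g, tt, buf,
                               dt = 2))
  }
  s1 <- run(1); s10 <- run(10)
  expect_equal(s10, s1, tolerance = 0.01)
})

test_that("noise injection is seed-stable with the stated magnitude", {
  net <- scheme_network("noP15")
  g <- cell_geometry(n_points = 150)
  sv <- simulate_lamm(net, c(O = 1.5e-6, R = 3e-6), g,
                      times = seq(600, 2400, 600), buf, dt = 4)
  expect_identical(add_noise(sv, 0, 1)$absorbance, sv$absorbance)
  n1 <- add_noise(sv, 0.005, 42)
  n2 <- add_noise(sv, 0.005, 42)
  expect_identical(n1$absorbance, n2$absorbance)
  resid <- n1$absorbance - sv$absorbance
  expect_gt(length(resid), 1e4 / 20)
  expect_equal(sd(resid), 0.005, tolerance = 0.05)
  # different seeds give different draws
  expect_false(identical(add_noise(sv, 0.005, 43)$absorbance, n1$absorbance))
})

test_that("transport method recovers a single-species s within 1 percent", {
  g <- cell_geometry(n_points = 250)
  tt <- seq(300, 2400, 300)
  D <- diffusion_from_s(2.32, 87.8, 0.711, buf)
  sim <- simulate_lamm_single(2.32, D, g, tt, loading = 0.5, dt = 2)
  sw <- transport_sw(as_scanset(sim$radii, tt, sim$profiles, g, buf))
  expect_equal(sw, 2.32, tolerance = 0.01)
  # robust to realistic noise
  svn <- add_noise(as_scanset(sim$radii, tt, sim$profiles, g, buf),
                   0.005, 7)
  expect_equal(transport_sw(svn), 2.32, tolerance = 0.03)
  # pure buffer: no plateau, an error
  blank <- as_scanset(sim$radii, tt, sim$profiles * 0, g, buf)
  expect_error(transport_sw(blank), "plateau")
})
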