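test_that("free ligand solves the binding quadratic", {
  # no binding or no macromolecule: all ligand free
  expect_equal(free_ligand(9e-6, 1.5e-6, 1, 0)$free, 9e-6)
  expect_equal(free_ligand(9e-6, 0, 1, 1.2e7)$free, 9e-6, tolerance = 1e-10)
  # agreement with a bisection oracle across a log grid
  for (K in c(1e5, 1.2e7, 1e9)) for (M in c(5e-7, 2e-6, 1e-5))
    for (X in c(1e-7, 3e-6, 2e-5)) for (n in c(1, 2)) {
      x_oracle <- free_ligand_bisect(X, M, n, K)
      expect_equal(free_ligand(X, M, n, K)$free, x_oracle,
                   tolerance = 1e-10)
    }
})

test_that("saturation fractions at six-fold peptide excess", {
  occ1 <- free_ligand(9e-6, 1.5e-6, 1, 1.2e7)$occupancy
  occ2 <- free_ligand(12e-6, 2e-6, 1, 1.2e7)$occupancy
  expect_equal(round(100 * occ1, 1), 98.9)
  expect_equal(round(100 * occ2, 1), 99.2)
})

test_that("total heat has the right endpoints and a hand-checked midpoint", {
  mod <- itc_model(n = 1, K_obs = 1.2e7, dH = -5.2, V0 = 1.4)
  expect_equal(total_heat(0, 2e-6, mod), 0)
  # saturation at V0 dH n M_tot (in ucal)
  expect_equal(total_heat(1, 2e-6, mod), 1.4 * -5.2 * 2e-6 * 1e6,
               tolerance = 1e-4)
  # monotone in X_tot
  q <- total_heat(seq(0, 1e-5, length.out = 40), 2e-6, mod)
  expect_true(all(diff(q) < 0))  # exothermic: increasingly negative
  # midpoint by explicit quadratic solve
  x <- free_ligand_bisect(2e-6, 2e-6, 1, 1.2e7)
  q_hand <- 1.4 * -5.2 * 2e-6 * (1.2e7 * x / (1 + 1.2e7 * x)) * 1e6
  expect_equal(total_heat(2e-6, 2e-6, mod), q_hand, tolerance = 1e-8)
})

test_that("differential heats apply the displacement correction", {
  Q <- c(-2, -3.5, -4.2, -4.5)
  # no displacement: first differences
  expect_equal(differential_heats(Q, rep(1e-9, 4), 1.4),
               c(-2, -1.5, -0.7, -0.3), tolerance = 1e-6)
  # constant Q: dQ_i = (dV_i/V0) Q
  Qc <- rep(-3, 5)
  dv <- rep(14, 5)   # ul
  dq <- differential_heats(Qc, dv, 1.4)
  expect_equal(dq[-1], rep(0.014 / 1.4 * -3, 4), tolerance = 1e-12)
  # telescoping bookkeeping: removing the displacement term recovers Q_N
  dv2 <- rep(20, 14)
  mod <- itc_model(1, 1.2e7, -5.2)
  tit <- titration(dv2, 50e-6, 2e-6)
  conc <- titration_concentrations(tit)
  Q2 <- total_heat(conc$X_tot, conc$M_tot, mod)
  dq2 <- differential_heats(Q2, dv2, 1.4)
  qprev <- c(0, Q2[-length(Q2)])
  disp <- (dv2 * 1e-3 / 1.4) * (Q2 + qprev) / 2
  expect_equal(sum(dq2 - disp), Q2[length(Q2)], tolerance = 1e-10)
})

test_that("cell bookkeeping dilutes macromolecule and accumulates ligand", {
  tit <- titration(rep(20, 14), 50e-6, 2e-6)
  conc <- titration_concentrations(tit)
  expect_true(all(diff(conc$M_tot) < 0))
  expect_true(all(diff(conc$X_tot) > 0))
  # total delivered ligand bounds the cell concentration
  expect_lt(max(conc$X_tot), 50e-6 * sum(tit$injection_volumes) * 1e-3 / 1.4)
})

test_that("noiseless titrations are recovered exactly and blanks cancel", {
  fx <- gen_itc(noise_sd = 0)
  ft <- fit_itc(fx$titration)
  expect_equal(coef(ft)[["K_obs"]], 1.2e7, tolerance = 1e-5)
  expect_equal(coef(ft)[["dH"]], -5.2, tolerance = 1e-6)
  expect_equal(coef(ft)[["n"]], 1, tolerance = 1e-6)
  # generator chain consistency: heats equal the forward model chain
  conc <- titration_concentrations(fx$titration)
  mod <- itc_model(1, 1.2e7, -5.2)
  q <- total_heat(conc$X_tot, conc$M_tot, mod)
  expect_equal(fx$titration$heats,
               differential_heats(q, fx$titration$injection_volumes, 1.4),
               tolerance = 1e-10)
  # adding a constant blank heat and subtracting it leaves the fit unchanged
  tit_b <- fx$titration
  tit_b$heats <- tit_b$heats + 0.35
  ft_b <- fit_itc(tit_b, blank = rep(0.35, length(tit_b$heats)))
  expect_equal(coef(ft_b), coef(ft), tolerance = 1e-6)
})

test_that("parameter recovery over 20 seeds at 0.1 ucal noise", {
  errK <- errH <- numeric(20)
  for (i in 1:20) {
    fx <- gen_itc(seed = 300 + i)
    ft <- fit_itc(fx$titration)
    errK[i] <- abs(coef(ft)[["K_obs"]] - 1.2e7) / 1.2e7
    errH[i] <- abs(coef(ft)[["dH"]] + 5.2) / 5.2
  }
  expect_lt(median(errK), 0.15)
  expect_lt(median(errH), 0.03)
})

test_that("degenerate designs trigger the c-value warning", {
  fx <- gen_itc(K = 100, noise_sd = 0)   # c-value far below 1
  expect_warning(fit_itc(fx$titration), "c-value")
})
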