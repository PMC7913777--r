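buf <- btp_buffer()

test_that("species-mode equilibrium profiles evaluate the exponential model", {
  spd <- data.frame(molar_mass = 43.9, vbar = 0.711, amplitude = 0.3,
                    fixed_mass = TRUE)
  spec <- se_model_spec("species", species = spd, baseline = 0.02)
  radii <- seq(6.5, 7.0, 0.005)
  # zero rotor speed: constant sum of amplitudes plus baseline
  expect_equal(predict_profile_species(spec, radii, 0, buf),
               rep(0.32, length(radii)))
  # at the reference radius the value is A0 + baseline regardless of speed
  a <- predict_profile_species(spec, radii, 25000, buf, meniscus = 6.5)
  expect_equal(a[1], 0.32, tolerance = 1e-12)
  # hand-evaluated exponent at r = 7.0 in a unit-density buffer
  b1 <- buffer_state(density = 1, viscosity = 1, temperature = 298.15)
  sig <- sigma_oracle(43.9, 0.711, 1, 25000)
  a7 <- predict_profile_species(spec, c(6.5, 7.0), 25000, b1, meniscus = 6.5)
  expect_equal(a7[2], 0.3 * exp(sig * (49 - 42.25)) + 0.02, tolerance = 1e-10)
})

test_that("dimer-tetramer profile: exponent doubling and L = 0 reduction", {
  radii <- seq(6.7, 7.0, 0.003)
  spec <- se_model_spec("dimer-tetramer", M_di = 43.9, vbar = 0.711,
                        L_obs = 2.16e5, C_di_r0 = 2e-6,
                        signal_coef = 1.272e5, baseline = 0)
  a <- predict_profile_dimer_tetramer(spec, radii, 25000, buf)
  cdi <- attr(a, "C_di"); ctet <- attr(a, "C_tet")
  # tetramer exponent is exactly twice the dimer exponent at every radius
  expect_equal(log(ctet / (2.16e5 * 2e-6^2)),
               2 * log(cdi / 2e-6), tolerance = 1e-10)
  # L = 0 equals a single dimer species
  spec0 <- se_model_spec("dimer-tetramer", M_di = 43.9, vbar = 0.711,
                         L_obs = 0, C_di_r0 = 2e-6,
                         signal_coef = 1.272e5, baseline = 0.01)
  sp1 <- se_model_spec("species",
                       species = data.frame(molar_mass = 43.9, vbar = 0.711,
                                            amplitude = 1.272e5 * 2e-6),
                       baseline = 0.01)
  expect_equal(as.numeric(predict_profile_dimer_tetramer(spec0, radii, 25000, buf)),
               predict_profile_species(sp1, radii, 25000, buf),
               tolerance = 1e-12)
  expect_error(se_model_spec("dimer-tetramer", M_di = 43.9, vbar = 0.711,
                             L_obs = -1, C_di_r0 = 1e-6, signal_coef = 1),
               "L_obs")
})

test_that("dimer-tetramer profile equals the matching two-species profile", {
  # cross-model equivalence: amplitudes C and L C^2 with M2 = 2 M_di
  radii <- seq(6.7, 7.0, 0.003)
  C <- 1.5e-6; L <- 2.16e5; coefd <- 1.272e5
  spec_dt <- se_model_spec("dimer-tetramer", M_di = 43.9, vbar = 0.711,
                           L_obs = L, C_di_r0 = C, signal_coef = coefd,
                           baseline = 0)
  spec_2s <- se_model_spec("species", species = data.frame(
    molar_mass = c(43.9, 87.8), vbar = 0.711,
    amplitude = c(coefd * C, 2 * coefd * L * C^2)), baseline = 0)
  expect_equal(as.numeric(predict_profile_dimer_tetramer(spec_dt, radii, 25000, buf)),
               predict_profile_species(spec_2s, radii, 25000, buf),
               tolerance = 1e-12)
})

test_that("species fractions solve the dimer-tetramer mass balance", {
  expect_equal(species_fractions(0, 4e-6), c(dimer = 1, tetramer = 0))
  # hand-solved quadratic at the reference condition
  L <- 2.16e5; R <- 4e-6
  cdi <- (-1 + sqrt(1 + 8 * L * R)) / (4 * L)
  expect_equal(species_fractions(L, R)[["tetramer"]], 2 * L * cdi^2 / R,
               tolerance = 1e-12)
  expect_equal(species_fractions(L, R)[["tetramer"]], 0.4754, tolerance = 2e-4)
  # fractions sum to one and satisfy detailed consistency [R4] = L [R2]^2
  for (Lx in c(1e3, 2.16e5, 1e7)) for (Rx in c(1e-7, 4e-6, 2e-5)) {
    f <- species_fractions(Lx, Rx)
    expect_equal(sum(f), 1, tolerance = 1e-12)
    r2 <- f[["dimer"]] * Rx
    r4 <- f[["tetramer"]] * Rx / 2
    expect_equal(r4, Lx * r2^2, tolerance = 1e-9)
  }
  # monotone saturation toward pure tetramer
  f_lo <- species_fractions(2.16e5, 1e-7)[["tetramer"]]
  f_hi <- species_fractions(2.16e5, 1e-1)[["tetramer"]]
  expect_lt(f_lo, f_hi)
  expect_gt(f_hi, 0.99)
})

test_that("column total signal matches analytic integrals and conservation", {
  radii <- seq(6.7, 7.0, 0.003)
  flat <- se_scan(radii, rep(0.4, length(radii)), 20000, 6.7, 7.0)
  expect_equal(column_total_signal(flat), 0.4 * (7.0^2 - 6.7^2) / 2,
               tolerance = 1e-6)
  zero <- se_scan(radii, rep(0, length(radii)), 20000, 6.7, 7.0)
  expect_equal(column_total_signal(zero), 0)
  # a conserved one-species system gives equal integrals at two speeds
  ints <- vapply(c(20000, 28000), function(rpm) {
    sig <- sigma_oracle(43.9, 0.711, buf$density, rpm)
    a0 <- conserved_amplitude(0.3, sig, 6.7, 7.0)
    spec <- se_model_spec("species", species = data.frame(
      molar_mass = 43.9, vbar = 0.711, amplitude = a0), baseline = 0)
    column_total_signal(se_scan(radii,
                                predict_profile_species(spec, radii, rpm, buf),
                                rpm, 6.7, 7.0))
  }, 0)
  expect_equal(ints[1], ints[2], tolerance = 1e-3)
  short <- se_scan(radii[1:30], rep(1, 30), 20000, 6.7, 7.0)
  expect_warning(column_total_signal(short), "cover")
})

test_that("global fit recovers exactly on noiseless dimer-tetramer data", {
  fx <- gen_se(noise_sd = 0, baseline_range = c(0, 0), seed = 5)
  spec <- se_model_spec("dimer-tetramer", M_di = 43.9, vbar = 0.711,
                        L_obs = 5e4, signal_coef = fx$truth$signal_coef)
  fit <- fit_se(fx$scans, spec, btp_buffer(), n_starts = 2)
  expect_true(fit$converged)
  expect_lt(max(fit$rmsd), 1e-8)
  expect_equal(coef(fit)[["L_obs"]], 2.16e5, tolerance = 1e-6)
})

test_that("global fit recovers a floated molecular weight within 2 percent", {
  # two species, 43.9 kDa fixed + 87.8 kDa floated, noise SD 0.005
  radii <- seq(6.7, 7.0, 0.003)
  scans <- list()
  k <- 0
  for (rpm in c(20000, 25000, 30000)) {
    k <- k + 1
    a <- rep(0, length(radii))
    for (sp in list(c(43.9, 0.2), c(87.8, 0.15))) {
      sig <- sigma_oracle(sp[1], 0.711, buf$density, rpm)
      a0 <- conserved_amplitude(sp[2], sig, 6.7, 7.0)
      a <- a + a0 * exp(sig * (radii^2 - 6.7^2))
    }
    set.seed(40 + k)
    scans[[k]] <- se_scan(radii, a + rnorm(length(a), 0, 0.005),
                          rpm, 6.7, 7.0)
  }
  spec <- se_model_spec("species", species = data.frame(
    molar_mass = c(43.9, 70), vbar = 0.711, amplitude = c(0.05, 0.05),
    fixed_mass = c(TRUE, FALSE)))
  fit <- fit_se(scans, spec, buf, n_starts = 4)
  expect_equal(coef(fit)[["M.2"]], 87.8, tolerance = 0.02)
  expect_equal(coef(fit)[["M.1"]], 43.9)   # stayed fixed
})

test_that("L_obs recovery under noise: 20 seeded replicates", {
  errs <- covered <- numeric(20)
  for (i in 1:20) {
    fx <- gen_se(seed = 1000 + i)
    spec <- se_model_spec("dimer-tetramer", M_di = 43.9, vbar = 0.711,
                          L_obs = 1e5, signal_coef = fx$truth$signal_coef)
    fit <- fit_se(fx$scans, spec, btp_buffer(), n_starts = 3)
    L <- coef(fit)[["L_obs"]]
    errs[i] <- abs(L - 2.16e5) / 2.16e5
    covered[i] <- abs(L - 2.16e5) <= 1.96 * fit$se[["L_obs"]]
  }
  expect_lt(median(errs), 0.10)
  expect_gte(sum(covered), 18)
})

test_that("mass-conservation penalty ties channel loadings across speeds", {
  fx <- gen_se(seed = 9)
  spec <- se_model_spec("dimer-tetramer", M_di = 43.9, vbar = 0.711,
                        L_obs = 1e5, signal_coef = fx$truth$signal_coef)
  fit <- fit_se(fx$scans, spec, btp_buffer(), conservation_weight = 1,
                n_starts = 2)
  expect_true(fit$converged)
  expect_equal(coef(fit)[["L_obs"]], 2.16e5, tolerance = 0.1)
})
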