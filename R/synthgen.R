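# Seeded generators that emulate the experimental designs: multi-speed,
# multi-loading sedimentation equilibrium of self-associating RecR;
# sedimentation velocity titrations of RecO with RecR under the assembly
# network; and P15 -> RecO ITC titrations. Every generator returns its
# ground-truth parameters alongside the data.

#' Generate a sedimentation-equilibrium fixture (dimer-tetramer)
#'
#' Emulates the equilibrium design: several loading concentrations spun to
#' equilibrium at several rotor speeds in six-channel cells, each channel
#' mass-conserving (the reference-radius dimer concentration is solved so
#' the sector-average concentration equals the loading), with per-scan
#' baseline offsets and Gaussian noise.
#'
#' @param L_obs True tetramerization constant, M^-1.
#' @param loadings_uM Loading concentrations, uM RecR monomer.
#' @param speeds_rpm Rotor speeds, rpm.
#' @param M_di Dimer molar mass, kDa.
#' @param vbar Partial specific volume, ml/g.
#' @param extinction Extinction per RecR monomer, M^-1 cm^-1.
#' @param pathlength Optical pathlength, cm.
#' @param noise_sd Gaussian noise SD, AU.
#' @param baseline_range Per-scan baselines drawn uniformly in this range,
#'   AU.
#' @param buffer A [buffer_state].
#' @param channels List of `c(meniscus, bottom)` per loading, cm.
#' @param dr Radial spacing, cm.
#' @param seed Integer seed.
#' @return List with `scans` (list of [se_scan]) and `truth`.
#' @export
gen_se <- function(L_obs = 2.16e5, loadings_uM = c(4, 8, 12),
                   speeds_rpm = c(20000, 25000, 30000),
                   M_di = 43.9, vbar = 0.711, extinction = 5.3e4,
                   pathlength = 1.2, noise_sd = 0.005,
                   baseline_range = c(-0.01, 0.01),
                   buffer = btp_buffer(),
                   channels = list(c(5.9, 6.2), c(6.3, 6.6), c(6.7, 7.0)),
                   dr = 0.003, seed = 1) {
  stopifnot(length(channels) >= length(loadings_uM), L_obs >= 0)
  signal_coef <- 2 * extinction * pathlength    # AU per molar dimer
  scans <- list()
  baselines <- c()
  k <- 0
  for (i in seq_along(loadings_uM)) {
    ch <- channels[[i]]
    radii <- seq(ch[1], ch[2], by = dr)
    r_tot <- loadings_uM[i] * 1e-6 / 2          # dimer units, M
    for (rpm in speeds_rpm) {
      k <- k + 1
      sig <- se_sigma(M_di, vbar, rpm, buffer)
      # mass conservation: sector-average concentration equals loading
      wints <- function(cc) {
        spec <- se_model_spec("dimer-tetramer", M_di = M_di, vbar = vbar,
                              L_obs = L_obs, C_di_r0 = cc,
                              signal_coef = 1, baseline = 0, r0 = ch[1])
        prof <- predict_profile_dimer_tetramer(spec, radii, rpm, buffer)
        num <- sum(diff(radii) * (prof[-1] * radii[-1] +
                                    prof[-length(prof)] * radii[-length(radii)]) / 2)
        den <- (ch[2]^2 - ch[1]^2) / 2
        num / den - r_tot
      }
      c_r0 <- stats::uniroot(wints, c(r_tot * 1e-12, r_tot),
                             tol = r_tot * 1e-14)$root
      noise <- with_substream_noise(seed, k, length(radii) + 1)
      b_k <- baseline_range[1] +
        (stats::pnorm(noise[1])) * diff(baseline_range)
      spec <- se_model_spec("dimer-tetramer", M_di = M_di, vbar = vbar,
                            L_obs = L_obs, C_di_r0 = c_r0,
                            signal_coef = signal_coef, baseline = b_k,
                            r0 = ch[1])
      a <- as.numeric(predict_profile_dimer_tetramer(spec, radii, rpm, buffer))
      a <- a + noise_sd * noise[-1]
      scans[[k]] <- se_scan(radii, a, rpm, meniscus = ch[1], bottom = ch[2],
                            channel = LETTERS[i])
      baselines <- c(baselines, b_k)
    }
  }
  list(scans = scans,
       truth = list(L_obs = L_obs, M_di = M_di, vbar = vbar,
                    loadings_uM = loadings_uM, speeds_rpm = speeds_rpm,
                    signal_coef = signal_coef, noise_sd = noise_sd,
                    baselines = baselines, seed = seed))
}

#' Built-in network fixtures of the velocity titration designs
#'
#' `"noP15"` carries the constants that best describe the RecO/RecR
#' titration in the absence of the SSB-Ct peptide (K3 = 5e5, K4 = 4e8
#' M^-1, positive cooperativity); `"plusP15"` the constants with the
#' peptide bound (K3 = 2.5e8, K4 = 1e7 M^-1, negative cooperativity).
#' Both share L_obs = 2.16e5 M^-1, K2 = 10 M^-1 and k_off = 0.01 s^-1.
#'
#' @param which `"noP15"` or `"plusP15"`.
#' @return A [reaction_network].
#' @export
scheme_network <- function(which = c("noP15", "plusP15")) {
  which <- match.arg(which)
  if (which == "noP15")
    reaction_network(L_obs = 2.16e5, K2 = 10, K3 = 5e5, K4 = 4e8)
  else
    reaction_network(L_obs = 2.16e5, K2 = 10, K3 = 2.5e8, K4 = 1e7)
}

#' Generate a sedimentation-velocity fixture (reacting system)
#'
#' Simulates the velocity titration design: RecO at fixed concentration
#' titrated with RecR at a molar ratio, 42,000 rpm, meniscus 6.14 cm,
#' bottom 7.2 cm, with Gaussian noise of SD 0.005 AU.
#'
#' @param network A [reaction_network] or fixture name for
#'   [scheme_network].
#' @param ratio RecR:RecO molar ratio (monomers), e.g. 6 for 1:6.
#' @param O_uM RecO concentration, uM.
#' @param times Scan times, s.
#' @param geometry A [cell_geometry].
#' @param buffer A [buffer_state].
#' @param noise_sd Noise SD, AU.
#' @param seed Integer seed.
#' @param ... Passed to [simulate_lamm].
#' @return List with `scans` (an `sv_scanset`) and `truth`.
#' @export
gen_sv <- function(network = "noP15", ratio = 6, O_uM = 1.5,
                   times = seq(60, 3600, by = 60),
                   geometry = cell_geometry(), buffer = btp_buffer(),
                   noise_sd = 0.005, seed = 1, ...) {
  if (is.character(network)) network <- scheme_network(network)
  totals <- c(O = O_uM * 1e-6, R = ratio * O_uM * 1e-6)
  clean <- simulate_lamm(network, totals, geometry, times, buffer, ...)
  noisy <- add_noise(clean, noise_sd, seed)
  list(scans = noisy,
       truth = list(K = network$K, k_off = network$k_off,
                    totals = totals, ratio = ratio,
                    noise_sd = noise_sd, seed = seed))
}

#' Generate an ITC fixture (P15 into RecO)
#'
#' Emulates the calorimetric design: ligand at `syringe_uM` titrated into
#' macromolecule at `cell_uM` with a regular injection schedule; returns
#' the noisy titration, a blank (dilution-only, zero binding signal)
#' titration, and the truth record.
#'
#' @param n,K,dH True stoichiometry, association constant (M^-1) and
#'   enthalpy (kcal/mol).
#' @param cell_uM Macromolecule concentration in the cell, uM.
#' @param syringe_uM Ligand concentration in the syringe, uM.
#' @param injections Injection volumes, ul.
#' @param V0 Cell volume, ml.
#' @param noise_sd Heat noise SD, ucal.
#' @param seed Integer seed.
#' @return List with `titration`, `blank` and `truth`.
#' @export
gen_itc <- function(n = 1, K = 1.2e7, dH = -5.2, cell_uM = 2,
                    syringe_uM = 50, injections = rep(20, 14), V0 = 1.4,
                    noise_sd = 0.1, seed = 1) {
  model <- itc_model(n, K, dH, V0)
  tit <- titration(injections, syringe_uM * 1e-6, cell_uM * 1e-6, V0 = V0)
  sim <- simulate_titration(model, tit, noise_sd = noise_sd, seed = seed)
  blank_tit <- titration(injections, syringe_uM * 1e-6, 0, V0 = V0)
  blank <- simulate_titration(itc_model(n, 0, 0, V0), blank_tit,
                              noise_sd = noise_sd, seed = seed + 1)
  list(titration = sim, blank = blank,
       truth = list(n = n, K = K, dH = dH, cell_uM = cell_uM,
                    syringe_uM = syringe_uM, noise_sd = noise_sd,
                    seed = seed))
}
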