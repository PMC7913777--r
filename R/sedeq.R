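# Sedimentation-equilibrium forward models and global NLLS fitting.
#
# The radial absorbance profile of species i at equilibrium is
#   A_i(r) = A_i(r0) * exp[ sigma_i * (r^2 - r0^2) ],
#   sigma_i = M_i (1 - vbar_i rho) omega^2 / (2 R T)   [cm^-2]
# and a reversible dimer-tetramer system obeys, in dimer-unit concentrations,
#   C(r) = C_di(r0) e^{sigma_di dr2} + L_obs C_di(r0)^2 e^{2 sigma_di dr2}.

#' One sedimentation-equilibrium scan
#'
#' @param radii Strictly increasing radial positions, cm.
#' @param absorbance Absorbance values, AU, same length as `radii`.
#' @param rotor_speed Rotor speed, rpm.
#' @param meniscus,bottom Channel limits, cm; must bracket the radii.
#' @param wavelength Detection wavelength, nm.
#' @param channel Channel label (scans of one channel share a loading).
#' @param time Elapsed time, s (only meaningful for velocity scans).
#' @return An object of class `"se_scan"`.
#' @export
se_scan <- function(radii, absorbance, rotor_speed, meniscus, bottom,
                    wavelength = 230, channel = "A", time = NA_real_) {
  stopifnot(length(radii) == length(absorbance), length(radii) >= 20,
            all(diff(radii) > 0))
  if (!(meniscus < radii[1] + 1e-9 && radii[length(radii)] <= bottom + 1e-9))
    stop("radii must lie within [meniscus, bottom]")
  structure(list(radii = radii, absorbance = absorbance,
                 rotor_speed = rotor_speed, meniscus = meniscus,
                 bottom = bottom, wavelength = wavelength,
                 channel = channel, time = time),
            class = "se_scan")
}

#' @export
print.se_scan <- function(x, ...) {
  cat(sprintf("se_scan: channel %s, %d rpm, %d points, r in [%.3f, %.3f] cm\n",
              x$channel, x$rotor_speed, length(x$radii),
              min(x$radii), max(x$radii)))
  invisible(x)
}

#' Reduced radial exponent sigma = M(1 - vbar rho) omega^2 / (2RT)
#'
#' @param molar_mass kDa.
#' @param vbar ml/g.
#' @param rotor_speed rpm.
#' @param buffer A [buffer_state].
#' @return sigma in cm^-2.
#' @export
se_sigma <- function(molar_mass, vbar, rotor_speed, buffer) {
  omega <- rpm_to_omega(rotor_speed)
  kda_to_gmol(buoyant_factor(molar_mass, vbar, buffer)) * omega^2 /
    (2 * .RGAS_CGS * buffer$temperature)
}

#' Model specification for sedimentation-equilibrium fitting
#'
#' In `"species"` mode the model is a sum of independent exponentials, one per
#' species row; in `"dimer-tetramer"` mode it is a reversibly associating
#' dimer/tetramer pair governed by a single constant `L_obs`.
#'
#' @param mode `"species"` or `"dimer-tetramer"`.
#' @param species For `"species"` mode, a data frame with columns
#'   `molar_mass` (kDa), `vbar`, `amplitude` (reference-radius absorbance),
#'   and logical `fixed_mass` (TRUE keeps the mass constant during fitting).
#' @param M_di Dimer molar mass, kDa (dimer-tetramer mode).
#' @param vbar Partial specific volume (dimer-tetramer mode), ml/g.
#' @param L_obs Tetramerization constant [T]/[D]^2, M^-1.
#' @param C_di_r0 Dimer concentration at the reference radius, M.
#' @param signal_coef Signal per molar dimer (extinction x pathlength),
#'   AU M^-1; the tetramer contributes twice this per mole.
#' @param baseline Baseline offset, AU (one per scan when fitting).
#' @param r0 Reference radius, cm; `NULL` means the scan meniscus.
#' @return An object of class `"se_model_spec"`.
#' @export
se_model_spec <- function(mode = c("species", "dimer-tetramer"),
                          species = NULL, M_di = NULL, vbar = NULL,
                          L_obs = NULL, C_di_r0 = NULL, signal_coef = NULL,
                          baseline = 0, r0 = NULL) {
  mode <- match.arg(mode)
  if (mode == "species") {
    stopifnot(is.data.frame(species),
              all(c("molar_mass", "vbar", "amplitude") %in% names(species)))
    if (is.null(species$fixed_mass)) species$fixed_mass <- TRUE
  } else {
    stopifnot(length(M_di) == 1, M_di > 0, !is.null(vbar))
    if (is.null(L_obs)) L_obs <- 0
    if (L_obs < 0) stop("L_obs must be >= 0")
  }
  structure(list(mode = mode, species = species, M_di = M_di, vbar = vbar,
                 L_obs = L_obs, C_di_r0 = C_di_r0,
                 signal_coef = signal_coef, baseline = baseline, r0 = r0),
            class = "se_model_spec")
}

#' @noRd
resolve_r0 <- function(spec, meniscus) if (is.null(spec$r0)) meniscus else spec$r0

#' Equilibrium absorbance profile of independent species
#'
#' @param spec An [se_model_spec] in `"species"` mode.
#' @param radii Radial positions, cm.
#' @param rotor_speed Rotor speed, rpm.
#' @param buffer A [buffer_state].
#' @param meniscus Channel meniscus, cm (default reference radius).
#' @return Absorbance at `radii`, AU.
#' @export
predict_profile_species <- function(spec, radii, rotor_speed, buffer,
                                    meniscus = min(radii)) {
  stopifnot(inherits(spec, "se_model_spec"), spec$mode == "species")
  r0 <- resolve_r0(spec, meniscus)
  dr2 <- radii^2 - r0^2
  a <- rep(spec$baseline, length(radii))
  for (i in seq_len(nrow(spec$species))) {
    sig <- se_sigma(spec$species$molar_mass[i], spec$species$vbar[i],
                    rotor_speed, buffer)
    a <- a + spec$species$amplitude[i] * exp(sig * dr2)
  }
  a
}

#' Equilibrium profile of a reversible dimer-tetramer system
#'
#' Returns the absorbance profile implied by the dimer-tetramer constant;
#' the tetramer exponent is exactly twice the dimer exponent. The molar
#' concentration profiles of dimer and tetramer are attached as attributes
#' `"C_di"` and `"C_tet"`.
#'
#' @inheritParams predict_profile_species
#' @param spec An [se_model_spec] in `"dimer-tetramer"` mode.
#' @return Absorbance at `radii`, AU.
#' @export
predict_profile_dimer_tetramer <- function(spec, radii, rotor_speed, buffer,
                                           meniscus = min(radii)) {
  stopifnot(inherits(spec, "se_model_spec"), spec$mode == "dimer-tetramer")
  if (spec$L_obs < 0) stop("L_obs must be >= 0")
  r0 <- resolve_r0(spec, meniscus)
  dr2 <- radii^2 - r0^2
  sig <- se_sigma(spec$M_di, spec$vbar, rotor_speed, buffer)
  c_di <- spec$C_di_r0 * exp(sig * dr2)
  c_tet <- spec$L_obs * spec$C_di_r0^2 * exp(2 * sig * dr2)
  a <- spec$signal_coef * (c_di + 2 * c_tet) + spec$baseline
  attr(a, "C_di") <- c_di
  attr(a, "C_tet") <- c_tet
  a
}

#' Dimer and tetramer mass fractions of a self-associating system
#'
#' Solves `R_tot = 2 L [D]^2 + [D]` for the free dimer concentration and
#' returns the mass fractions `f_di = [D]/R_tot` and `f_tet = 2 L [D]^2 /
#' R_tot`, which sum to one.
#'
#' @param L_obs Tetramerization constant, M^-1.
#' @param R_tot Total concentration in dimer units, M.
#' @return Named vector `c(dimer = , tetramer = )`.
#' @export
species_fractions <- function(L_obs, R_tot) {
  stopifnot(L_obs >= 0, R_tot > 0)
  if (L_obs == 0) return(c(dimer = 1, tetramer = 0))
  c_di <- (-1 + sqrt(1 + 8 * L_obs * R_tot)) / (4 * L_obs)
  f_di <- c_di / R_tot
  c(dimer = f_di, tetramer = 1 - f_di)
}

#' Sector-weighted total signal of a scan
#'
#' Trapezoidal evaluation of `integral A(r) r dr` over the scanned radii. In a
#' sector-shaped cell this is proportional to the total amount of absorbing
#' material, so for a conserved system it is the same at every rotor speed.
#'
#' @param scan An [se_scan].
#' @return Integral in AU cm^2.
#' @export
column_total_signal <- function(scan) {
  stopifnot(inherits(scan, "se_scan"))
  cover <- (max(scan$radii) - min(scan$radii)) / (scan$bottom - scan$meniscus)
  if (cover < 0.9)
    warning("scan radii cover only ", round(100 * cover),
            "% of the column; the integral underestimates the loading")
  r <- scan$radii
  a <- scan$absorbance
  sum(diff(r) * (a[-1] * r[-1] + a[-length(a)] * r[-length(r)]) / 2)
}

#' Global NLLS fit of sedimentation-equilibrium scans
#'
#' Fits all scans simultaneously by Levenberg-Marquardt least squares.
#' In `"dimer-tetramer"` mode the single association constant `L_obs` is
#' global across all scans while each scan has its own reference-radius dimer
#' concentration and baseline; `L_obs` and the concentrations are optimized
#' as log10 quantities so positivity needs no constraints. In `"species"`
#' mode the species molar masses are global (each either fixed or floated)
#' with per-scan amplitudes and baselines.
#'
#' @param scans List of [se_scan] objects.
#' @param spec An [se_model_spec] providing the model structure and starting
#'   values (`L_obs` start is refined by log-uniform multistart).
#' @param buffer A [buffer_state].
#' @param conservation_weight Weight of the optional mass-conservation
#'   penalty tying the model-implied column signal of scans sharing a channel
#'   to a common value across rotor speeds; 0 (default) disables it.
#' @param n_starts Number of multistart perturbations of the global
#'   association constant (log-uniform over +/- 2 decades).
#' @param seed Seed for the multistart draws.
#' @return An object of class `"se_fit"` with elements `coefficients`
#'   (named vector), `se` (asymptotic standard errors), `rmsd` (per scan, AU),
#'   `residuals`, `converged`, `spec`, `scans`.
#' @export
fit_se <- function(scans, spec, buffer, conservation_weight = 0,
                   n_starts = 8, seed = 1) {
  stopifnot(length(scans) >= 1, inherits(spec, "se_model_spec"))
  if (spec$mode == "dimer-tetramer")
    fit_se_dimer_tetramer(scans, spec, buffer, conservation_weight,
                          n_starts, seed)
  else
    fit_se_species(scans, spec, buffer, n_starts, seed)
}

#' @noRd
se_fit_result <- function(par, se, rmsd, residuals, converged, message,
                          spec, scans, objective) {
  structure(list(coefficients = par, se = se, rmsd = rmsd,
                 residuals = residuals, converged = converged,
                 message = message, spec = spec, scans = scans,
                 objective = objective),
            class = "se_fit")
}

#' @noRd
fit_se_dimer_tetramer <- function(scans, spec, buffer, conservation_weight,
                                  n_starts, seed) {
  ns <- length(scans)
  sig <- vapply(scans, function(sc)
    se_sigma(spec$M_di, spec$vbar, sc$rotor_speed, buffer), 0)
  dr2 <- lapply(scans, function(sc) sc$radii^2 - resolve_r0(spec, sc$meniscus)^2)
  coef_sig <- spec$signal_coef
  channels <- vapply(scans, function(sc) sc$channel, "")

  model_one <- function(lgL, lgC, b, k) {
    e1 <- exp(sig[k] * dr2[[k]])
    C <- 10^lgC
    coef_sig * (C * e1 + 2 * 10^lgL * C^2 * e1^2) + b
  }
  resid_fn <- function(p) {
    lgL <- p[1]
    res <- unlist(lapply(seq_len(ns), function(k)
      model_one(lgL, p[1 + k], p[1 + ns + k], k) - scans[[k]]$absorbance))
    if (conservation_weight > 0) {
      tot <- vapply(seq_len(ns), function(k) {
        sc <- scans[[k]]
        a <- model_one(lgL, p[1 + k], 0, k)   # baseline-free model signal
        r <- sc$radii
        sum(diff(r) * (a[-1] * r[-1] + a[-length(a)] * r[-length(r)]) / 2)
      }, 0)
      pen <- unlist(lapply(split(seq_len(ns), channels), function(idx)
        tot[idx] - mean(tot[idx])))
      res <- c(res, conservation_weight * pen)
    }
    res
  }

  # data-driven starts: meniscus absorbance sets the dimer scale
  lgC0 <- vapply(seq_len(ns), function(k) {
    a_men <- max(scans[[k]]$absorbance[1], 1e-4)
    log10(a_men / coef_sig)
  }, 0)
  lgL0 <- log10(max(spec$L_obs, 1))
  b0 <- rep(spec$baseline, ns)

  set.seed(seed)
  offsets <- c(0, runif(max(n_starts - 1, 0), -2, 2))
  best <- NULL
  for (off in offsets) {
    fit <- tryCatch(
      minpack.lm::nls.lm(c(lgL0 + off, lgC0, b0), fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 400, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) stop("all multistarts failed")
  p <- best$par
  vc <- tryCatch(vcov(best), error = function(e)
    matrix(NA_real_, length(p), length(p)))
  se_log <- sqrt(pmax(diag(vc), 0))
  L_hat <- 10^p[1]
  par <- c(L_obs = L_hat,
           stats::setNames(10^p[2:(1 + ns)], paste0("C_di_r0.", seq_len(ns))),
           stats::setNames(p[(2 + ns):(1 + 2 * ns)],
                           paste0("baseline.", seq_len(ns))))
  se <- c(L_obs = L_hat * log(10) * se_log[1],
          stats::setNames(10^p[2:(1 + ns)] * log(10) * se_log[2:(1 + ns)],
                          paste0("C_di_r0.", seq_len(ns))),
          stats::setNames(se_log[(2 + ns):(1 + 2 * ns)],
                          paste0("baseline.", seq_len(ns))))
  res_list <- lapply(seq_len(ns), function(k)
    model_one(p[1], p[1 + k], p[1 + ns + k], k) - scans[[k]]$absorbance)
  rmsd <- vapply(res_list, function(r) sqrt(mean(r^2)), 0)
  se_fit_result(par, se, rmsd, res_list,
                converged = best$info %in% 1:4, message = best$message,
                spec = spec, scans = scans, objective = best$deviance)
}

#' @noRd
fit_se_species <- function(scans, spec, buffer, n_starts, seed) {
  ns <- length(scans)
  sp <- spec$species
  np <- nrow(sp)
  floated <- which(!sp$fixed_mass)
  dr2 <- lapply(scans, function(sc) sc$radii^2 - resolve_r0(spec, sc$meniscus)^2)
  rpms <- vapply(scans, function(sc) sc$rotor_speed, 0)

  # parameters: log10 M for floated species, then per-scan per-species
  # log-amplitudes, then per-scan baselines
  unpack <- function(p) {
    m <- sp$molar_mass
    if (length(floated)) m[floated] <- 10^p[seq_along(floated)]
    amp <- matrix(10^p[length(floated) + seq_len(ns * np)], nrow = ns)
    b <- p[length(floated) + ns * np + seq_len(ns)]
    list(m = m, amp = amp, b = b)
  }
  model_one <- function(q, k) {
    a <- rep(q$b[k], length(dr2[[k]]))
    for (i in seq_len(np)) {
      s_i <- se_sigma(q$m[i], sp$vbar[i], rpms[k], buffer)
      a <- a + q$amp[k, i] * exp(s_i * dr2[[k]])
    }
    a
  }
  resid_fn <- function(p) {
    q <- unpack(p)
    unlist(lapply(seq_len(ns), function(k)
      model_one(q, k) - scans[[k]]$absorbance))
  }

  amp0 <- log10(pmax(rep(sp$amplitude, each = ns), 1e-5))
  p0 <- c(log10(sp$molar_mass[floated]), amp0, rep(spec$baseline, ns))
  set.seed(seed)
  best <- NULL
  for (j in seq_len(max(n_starts, 1))) {
    pj <- p0
    if (j > 1 && length(floated))
      pj[seq_along(floated)] <- p0[seq_along(floated)] + runif(length(floated), -0.5, 0.5)
    fit <- tryCatch(
      minpack.lm::nls.lm(pj, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 400, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) stop("all multistarts failed")
  q <- unpack(best$par)
  vc <- tryCatch(vcov(best), error = function(e)
    matrix(NA_real_, length(best$par), length(best$par)))
  se_log <- sqrt(pmax(diag(vc), 0))
  par <- c(stats::setNames(q$m, paste0("M.", seq_len(np))),
           stats::setNames(as.vector(q$amp),
                           paste0("A.", rep(seq_len(ns), np), ".",
                                  rep(seq_len(np), each = ns))),
           stats::setNames(q$b, paste0("baseline.", seq_len(ns))))
  se <- rep(NA_real_, length(par))
  names(se) <- names(par)
  if (length(floated))
    se[paste0("M.", floated)] <- q$m[floated] * log(10) * se_log[seq_along(floated)]
  res_list <- lapply(seq_len(ns), function(k)
    model_one(q, k) - scans[[k]]$absorbance)
  rmsd <- vapply(res_list, function(r) sqrt(mean(r^2)), 0)
  se_fit_result(par, se, rmsd, res_list,
                converged = best$info %in% 1:4, message = best$message,
                spec = spec, scans = scans, objective = best$deviance)
}

#' @export
print.se_fit <- function(x, ...) {
  cat("Global sedimentation-equilibrium fit (", x$spec$mode, " model)\n",
      sep = "")
  cat("  scans:", length(x$scans),
      " objective (SSR):", format(x$objective, digits = 6), "\n")
  if (x$spec$mode == "dimer-tetramer")
    cat(sprintf("  L_obs = %.4g +/- %.2g M^-1\n",
                x$coefficients["L_obs"], x$se["L_obs"]))
  cat("  per-scan RMSD (AU):", paste(format(x$rmsd, digits = 3),
                                     collapse = " "), "\n")
  if (!x$converged) cat("  WARNING: optimizer did not report convergence\n")
  invisible(x)
}

#' @export
coef.se_fit <- function(object, ...) object$coefficients

#' @export
residuals.se_fit <- function(object, ...) object$residuals

#' @export
summary.se_fit <- function(object, ...) {
  out <- data.frame(estimate = object$coefficients, se = object$se)
  cat("Coefficients:\n")
  print(out)
  invisible(out)
}
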