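# Isothermal titration calorimetry: forward model and fitting for a ligand X
# binding to n identical and independent sites on a macromolecule M.
#
#   Q_tot = V0 dH M_tot n K x / (1 + K x)          (total heat, cell frame)
#   X_tot = x + n K x / (1 + K x) * M_tot          (free-ligand quadratic)
#
# Heats are in microcalories externally; dH in kcal/mol; volumes in ml.

#' ITC binding model (n identical independent sites)
#'
#' @param n Sites per macromolecule.
#' @param K_obs Observed association constant, M^-1.
#' @param dH Binding enthalpy, kcal/mol.
#' @param V0 Calorimeter cell volume, ml.
#' @return An object of class `"itc_model"`.
#' @export
itc_model <- function(n, K_obs, dH, V0 = 1.4) {
  stopifnot(n > 0, K_obs >= 0, V0 > 0)
  structure(list(n = n, K_obs = K_obs, dH = dH, V0 = V0),
            class = "itc_model")
}

#' @export
print.itc_model <- function(x, ...) {
  cat(sprintf("ITC model: n = %.3g, K = %.4g M^-1, dH = %.3g kcal/mol, V0 = %.2f ml\n",
              x$n, x$K_obs, x$dH, x$V0))
  invisible(x)
}

#' A titration experiment
#'
#' @param injection_volumes Injection volumes, microliters.
#' @param syringe_conc Ligand concentration in the syringe, M.
#' @param cell_conc Initial macromolecule concentration in the cell, M.
#' @param heats Measured differential heats per injection, microcal
#'   (optional until fitting).
#' @param blank_heats Optional blank (dilution) heats, microcal.
#' @param V0 Cell volume, ml.
#' @return An object of class `"titration"`.
#' @export
titration <- function(injection_volumes, syringe_conc, cell_conc,
                      heats = NULL, blank_heats = NULL, V0 = 1.4) {
  stopifnot(all(injection_volumes > 0), syringe_conc >= 0, cell_conc >= 0,
            V0 > 0)
  if (!is.null(heats))
    stopifnot(length(heats) == length(injection_volumes))
  structure(list(injection_volumes = injection_volumes,
                 syringe_conc = syringe_conc, cell_conc = cell_conc,
                 heats = heats, blank_heats = blank_heats, V0 = V0),
            class = "titration")
}

#' @export
print.titration <- function(x, ...) {
  cat(sprintf("titration: %d injections (%.1f ul total), syringe %.3g M, cell %.3g M\n",
              length(x$injection_volumes), sum(x$injection_volumes),
              x$syringe_conc, x$cell_conc))
  invisible(x)
}

#' Free ligand concentration and site occupancy
#'
#' Solves the mass-balance quadratic
#' `X_tot = x + n K x/(1 + K x) M_tot` for the free ligand `x` and returns
#' the site occupancy `K x / (1 + K x)`. For a 1:1 system (`n = 1`) the
#' occupancy equals the fraction of macromolecule bound.
#'
#' @param X_tot Total ligand concentration, M.
#' @param M_tot Total macromolecule concentration, M.
#' @param n Sites per macromolecule.
#' @param K Association constant, M^-1.
#' @return List with `free` (M) and `occupancy` (0-1). Vectorized over
#'   `X_tot`/`M_tot`.
#' @export
free_ligand <- function(X_tot, M_tot, n, K) {
  stopifnot(all(X_tot >= 0), all(M_tot >= 0), n > 0, K >= 0)
  if (K == 0) return(list(free = X_tot, occupancy = rep(0, length(X_tot))))
  b <- 1 + K * (n * M_tot - X_tot)
  x <- (-b + sqrt(b^2 + 4 * K * X_tot)) / (2 * K)
  x <- pmax(x, 0)
  list(free = x, occupancy = K * x / (1 + K * x))
}

#' Total (integral) heat content of the cell
#'
#' `Q_tot = V0 dH n M_tot K x / (1 + K x)` with the free ligand from
#' [free_ligand]. Zero at `X_tot = 0`; saturates at `V0 dH n M_tot`.
#'
#' @param X_tot Total ligand, M (vectorized).
#' @param M_tot Total macromolecule, M.
#' @param model An [itc_model].
#' @return Total heat, microcal.
#' @export
total_heat <- function(X_tot, M_tot, model) {
  stopifnot(inherits(model, "itc_model"))
  fl <- free_ligand(X_tot, M_tot, model$n, model$K_obs)
  # V0[ml] * 1e-3 l * dH[kcal/mol] * 1e3 cal * ... * 1e6 ucal/cal
  model$V0 * model$dH * model$n * M_tot * fl$occupancy * 1e6
}

#' Convert integral heats to differential (per-injection) heats
#'
#' Applies the displacement correction for an overflow cell:
#' `dQ_i = Q_i - Q_{i-1} + (dV_i / V0) (Q_i + Q_{i-1}) / 2`,
#' accounting for the heat carried out of the active volume by the
#' displaced liquid.
#'
#' @param Q_tot Integral heats after each injection, microcal (`Q_0 = 0`).
#' @param injection_volumes Injection volumes, microliters.
#' @param V0 Cell volume, ml.
#' @return Differential heats per injection, microcal.
#' @export
differential_heats <- function(Q_tot, injection_volumes, V0 = 1.4) {
  stopifnot(length(Q_tot) == length(injection_volumes))
  qprev <- c(0, Q_tot[-length(Q_tot)])
  f <- injection_volumes * 1e-3 / V0          # ul -> ml
  Q_tot - qprev + f * (Q_tot + qprev) / 2
}

#' Cell concentrations after each injection
#'
#' Standard overflow-cell bookkeeping with instantaneous mixing: each
#' injection of volume `dV` dilutes the cell contents by the factor
#' `(1 - f/2) / (1 + f/2)` with `f = dV/V0`, and delivers syringe ligand
#' `X_syr * f / (1 + f/2)`.
#'
#' @param tit A [titration].
#' @return Data frame with per-injection `M_tot` and `X_tot` (M).
#' @export
titration_concentrations <- function(tit) {
  stopifnot(inherits(tit, "titration"))
  f <- tit$injection_volumes * 1e-3 / tit$V0
  d <- (1 - f / 2) / (1 + f / 2)
  ni <- length(f)
  M <- X <- numeric(ni)
  m <- tit$cell_conc; x <- 0
  for (i in seq_len(ni)) {
    m <- m * d[i]
    x <- x * d[i] + tit$syringe_conc * f[i] / (1 + f[i] / 2)
    M[i] <- m; X[i] <- x
  }
  data.frame(injection = seq_len(ni), M_tot = M, X_tot = X)
}

#' Simulate the differential heats of a titration
#'
#' Forward-evaluates the binding isotherm along the injection schedule and
#' converts integral to differential heats with the displacement correction.
#'
#' @param model An [itc_model].
#' @param tit A [titration] (its `heats` are ignored).
#' @param noise_sd Gaussian noise SD added to each differential heat,
#'   microcal.
#' @param seed Seed used when `noise_sd > 0`.
#' @return The [titration] with simulated `heats` filled in; the noiseless
#'   heats and concentrations are attached as attributes `"clean"` and
#'   `"concentrations"`.
#' @export
simulate_titration <- function(model, tit, noise_sd = 0, seed = 1) {
  stopifnot(inherits(model, "itc_model"), inherits(tit, "titration"))
  conc <- titration_concentrations(tit)
  q_tot <- total_heat(conc$X_tot, conc$M_tot, model)
  dq <- differential_heats(q_tot, tit$injection_volumes, tit$V0)
  heats <- dq
  if (noise_sd > 0) {
    heats <- heats + with_substream_noise(seed, 1L, length(dq)) * noise_sd
  }
  out <- tit
  out$heats <- heats
  attr(out, "clean") <- dq
  attr(out, "concentrations") <- conc
  out
}

#' Fit an n-site binding model to a titration
#'
#' Levenberg-Marquardt least squares of the displacement-corrected
#' differential-heat model against measured heats, over `(n, log10 K, dH)`.
#' Blank heats, when provided (either per-injection in `blank` or stored in
#' the titration), are subtracted first.
#'
#' @param tit A [titration] with `heats`.
#' @param blank Optional blank differential heats, microcal (single value or
#'   one per injection); defaults to `tit$blank_heats`.
#' @param start Optional named list with starting `n`, `K_obs`, `dH`.
#' @param n_starts Number of multistart values of `log10 K` tried around the
#'   start (spread over +/- 2 decades).
#' @return An object of class `"itc_fit"` with the fitted [itc_model],
#'   coefficients, standard errors, residuals, RMSD and the c-value
#'   diagnostic `K * M_tot * n`.
#' @export
fit_itc <- function(tit, blank = NULL, start = NULL, n_starts = 5) {
  stopifnot(inherits(tit, "titration"), !is.null(tit$heats))
  if (is.null(blank)) blank <- tit$blank_heats
  y <- tit$heats
  if (!is.null(blank)) y <- y - blank
  if (length(y) < 8) stop("need at least 8 injections")
  conc <- titration_concentrations(tit)

  resid_fn <- function(p) {
    mod <- itc_model(p[1], 10^p[2], p[3], tit$V0)
    q <- total_heat(conc$X_tot, conc$M_tot, mod)
    differential_heats(q, tit$injection_volumes, tit$V0) - y
  }

  dh0 <- if (is.null(start$dH)) sum(y) / (tit$V0 * tit$cell_conc * 1e6)
         else start$dH
  n0 <- if (is.null(start$n)) 1 else start$n
  lgK0 <- if (is.null(start$K_obs)) log10(2 / tit$cell_conc)
          else log10(start$K_obs)
  best <- NULL
  for (off in seq(-2, 2, length.out = max(n_starts, 1))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(c(n0, lgK0 + off, dh0), fn = resid_fn,
                         lower = c(0.05, 0, -1e3), upper = c(20, 14, 1e3),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) stop("all multistarts failed")
  p <- best$par
  mod <- itc_model(p[1], 10^p[2], p[3], tit$V0)
  vc <- tryCatch(vcov(best), error = function(e)
    matrix(NA_real_, 3, 3))
  sed <- sqrt(pmax(diag(vc), 0))
  coefs <- c(n = mod$n, K_obs = mod$K_obs, dH = mod$dH)
  ses <- c(n = sed[1], K_obs = mod$K_obs * log(10) * sed[2], dH = sed[3])
  res <- resid_fn(p)
  cval <- mod$K_obs * tit$cell_conc * mod$n
  if (cval < 1 || cval > 1000)
    warning("c-value ", format(cval, digits = 3),
            " outside [1, 1000]: titration carries little information on K")
  structure(list(model = mod, coefficients = coefs, se = ses,
                 residuals = res, rmsd = sqrt(mean(res^2)),
                 c_value = cval, titration = tit,
                 converged = best$info %in% 1:4, message = best$message),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat("ITC fit, n identical independent sites\n")
  cat(sprintf("  n  = %.3g +/- %.2g\n", x$coefficients["n"], x$se["n"]))
  cat(sprintf("  K  = %.4g +/- %.2g M^-1\n",
              x$coefficients["K_obs"], x$se["K_obs"]))
  cat(sprintf("  dH = %.4g +/- %.2g kcal/mol\n",
              x$coefficients["dH"], x$se["dH"]))
  cat(sprintf("  RMSD = %.3g ucal, c-value = %.3g\n", x$rmsd, x$c_value))
  if (!x$converged) cat("  WARNING: optimizer did not report convergence\n")
  invisible(x)
}

#' @export
coef.itc_fit <- function(object, ...) object$coefficients

#' @export
residuals.itc_fit <- function(object, ...) object$residuals

#' @export
summary.itc_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
plot.itc_fit <- function(x, ...) {
  tit <- x$titration
  conc <- titration_concentrations(tit)
  ratio <- conc$X_tot / conc$M_tot
  graphics::plot(ratio, tit$heats, pch = 19,
                 xlab = "molar ratio X/M", ylab = "heat per injection (ucal)",
                 ...)
  q <- total_heat(conc$X_tot, conc$M_tot, x$model)
  graphics::lines(ratio,
                  differential_heats(q, tit$injection_volumes, tit$V0))
  invisible(x)
}
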