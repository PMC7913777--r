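# Wyman linkage analysis of a pH-dependent tetramerization constant.
#
# Two dimers associate to a tetramer with constant L_obs = [T]/[D]^2.
# Proton binding to m sites on the tetramer and n sites on each dimer links
# the association constant to pH through binding polynomials:
#   L_obs(pH) = L0 * P_tet / P_di^2
# with P = (1 + k [H+])^sites for independent identical sites and
# P = 1 + (k [H+])^sites for fully cooperative sites.

#' Proton binding polynomial
#'
#' @param k Site protonation constant, M^-1.
#' @param pH Solution pH; `[H+] = 10^-pH`.
#' @param sites Number of protonation sites (>= 0).
#' @param cooperative If `TRUE`, the fully cooperative (all-or-none) form
#'   `1 + (k[H+])^sites`; otherwise the independent-sites form
#'   `(1 + k[H+])^sites`.
#' @return Polynomial value (unitless, >= 1). Vectorized over `pH`.
#' @export
binding_polynomial <- function(k, pH, sites, cooperative = FALSE) {
  stopifnot(k > 0, sites >= 0)
  if (sites == 0) return(rep(1, length(pH)))
  x <- k * 10^(-pH)
  if (cooperative) 1 + x^sites else (1 + x)^sites
}

#' Linkage model for a pH-dependent association constant
#'
#' @param L0 Association constant of the fully deprotonated system, M^-1.
#' @param k_tet Tetramer-site protonation constant, M^-1.
#' @param k_di Dimer-site protonation constant, M^-1.
#' @param m Number of tetramer protonation sites.
#' @param n Number of dimer protonation sites (per dimer).
#' @param coop_tet,coop_di Cooperative (all-or-none) protonation flags for
#'   the tetramer and dimer polynomials.
#' @return An object of class `"linkage_model"`.
#' @export
linkage_model <- function(L0, k_tet, k_di, m = 3, n = 2,
                          coop_tet = TRUE, coop_di = FALSE) {
  stopifnot(L0 > 0, k_tet > 0, k_di > 0, m >= 0, n >= 0)
  structure(list(L0 = L0, k_tet = k_tet, k_di = k_di, m = m, n = n,
                 coop_tet = coop_tet, coop_di = coop_di),
            class = "linkage_model")
}

#' @export
print.linkage_model <- function(x, ...) {
  cat(sprintf(
    "linkage model: L0 = %.4g M^-1, k_tet = %.4g (m = %d%s), k_di = %.4g (n = %d%s)\n",
    x$L0, x$k_tet, x$m, if (x$coop_tet) ", coop" else "",
    x$k_di, x$n, if (x$coop_di) ", coop" else ""))
  invisible(x)
}

#' log10 of the observed association constant at given pH
#'
#' Evaluates `log10 L_obs(pH) = log10 L0 + log10 P_tet - 2 log10 P_di`.
#' The high-pH limit is `log10 L0`; with a cooperative tetramer and
#' independent dimer sites the low-pH asymptotic slope is `2n - m`.
#'
#' @param model A [linkage_model].
#' @param pH Vector of pH values.
#' @return `log10 L_obs` at each pH.
#' @export
log_L_model <- function(model, pH) {
  stopifnot(inherits(model, "linkage_model"))
  log10(model$L0) +
    log10(binding_polynomial(model$k_tet, pH, model$m, model$coop_tet)) -
    2 * log10(binding_polynomial(model$k_di, pH, model$n, model$coop_di))
}

#' @export
predict.linkage_model <- function(object, pH, what = c("log10_L", "L"), ...) {
  what <- match.arg(what)
  v <- log_L_model(object, pH)
  if (what == "L") 10^v else v
}

#' Net proton uptake slope d(log10 L_obs)/d(pH)
#'
#' The pointwise slope of the linkage curve equals the net number of protons
#' taken up on tetramer formation (with a sign: uptake gives a negative
#' slope at high pH). Computed analytically; over an interval the mean slope
#' `(logL(b) - logL(a)) / (b - a)` is returned.
#'
#' @param model A [linkage_model].
#' @param pH Evaluation pH (ignored when `interval` is given).
#' @param interval Optional `c(a, b)` interval for a mean slope.
#' @return Slope in log10 units per pH unit (protons).
#' @export
proton_uptake_slope <- function(model, pH = NULL, interval = NULL) {
  stopifnot(inherits(model, "linkage_model"))
  if (!is.null(interval)) {
    stopifnot(length(interval) == 2, interval[2] != interval[1])
    v <- log_L_model(model, interval)
    return((v[2] - v[1]) / (interval[2] - interval[1]))
  }
  stopifnot(!is.null(pH))
  dpoly <- function(k, sites, coop) {
    # d log10 P / d pH
    if (sites == 0) return(rep(0, length(pH)))
    x <- k * 10^(-pH)
    if (coop) -sites * x^sites / (1 + x^sites) else -sites * x / (1 + x)
  }
  dpoly(model$k_tet, model$m, model$coop_tet) -
    2 * dpoly(model$k_di, model$n, model$coop_di)
}

#' Fit the linkage model to a (pH, L_obs) series
#'
#' Nonlinear least squares on `log10 L_obs` versus pH, with parameters
#' optimized as `log10 k_tet`, `log10 k_di` (and `log10 L0` if floated).
#' Rows flagged as upper limits are excluded from the residuals by default;
#' optionally they contribute a one-sided penalty when the model exceeds the
#' limit.
#'
#' When the data do not extend above the tetramer-site pKa, `L0` and `k_tet`
#' are confounded (only `L0 * k_tet^m` is determined) and an unconstrained
#' fit drifts along that ridge. The conventional normalization - the package
#' default - fixes `L0 = 1` M^-1 so the remaining parameters are identified;
#' pass `fix_L0 = NULL` to float it.
#'
#' @param data Data frame with columns `pH`, `L_obs` and optionally `SE` and
#'   logical/0-1 `upper_limit`.
#' @param m,n,coop_tet,coop_di Site counts and cooperativity flags (defaults:
#'   three cooperative tetramer sites, two independent dimer sites).
#' @param fix_L0 Fixed value of `L0` in M^-1, or `NULL` to float it.
#' @param weighted If `TRUE` and an `SE` column is present, residuals are
#'   weighted by the propagated uncertainties `SE / (L ln 10)` on the log
#'   scale; default unweighted.
#' @param upper_limit_penalty Weight of the one-sided penalty for
#'   upper-limit rows (0 = exclude them entirely, the default).
#' @return An object of class `"linkage_fit"`: the fitted [linkage_model],
#'   coefficient table with standard errors, residuals and RMSD.
#' @export
fit_linkage <- function(data, m = 3, n = 2, coop_tet = TRUE, coop_di = FALSE,
                        fix_L0 = 1, weighted = FALSE,
                        upper_limit_penalty = 0) {
  stopifnot(all(c("pH", "L_obs") %in% names(data)), all(data$L_obs > 0))
  ul <- if (!is.null(data$upper_limit)) as.logical(data$upper_limit)
        else rep(FALSE, nrow(data))
  use <- !ul
  float_L0 <- is.null(fix_L0)
  npar <- 2L + float_L0
  if (sum(use) < npar + 1)
    stop("need more usable points than parameters")
  pH <- data$pH
  y <- log10(data$L_obs)
  w <- rep(1, nrow(data))
  if (weighted && !is.null(data$SE))
    w <- 1 / (data$SE / (data$L_obs * log(10)))

  mk_model <- function(p) {
    L0 <- if (float_L0) 10^p[3] else fix_L0
    linkage_model(L0, 10^p[1], 10^p[2], m, n, coop_tet, coop_di)
  }
  resid_fn <- function(p) {
    mod <- mk_model(p)
    yhat <- log_L_model(mod, pH)
    r <- (yhat - y) * w
    out <- r[use]
    if (upper_limit_penalty > 0 && any(ul))
      out <- c(out, upper_limit_penalty * pmax(yhat[ul] - y[ul], 0))
    out
  }

  # data-driven starts: dimer pKa near the pH of maximal L_obs; tetramer pKa
  # one unit above the highest usable pH; L0 two decades below the last point
  p0 <- c(max(pH[use]) + 1, pH[use][which.max(y[use])])
  if (float_L0) p0 <- c(p0, y[use][which.max(pH[use])] - 2)
  fit <- minpack.lm::nls.lm(p0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  p <- fit$par
  mod <- mk_model(p)
  vc <- tryCatch(vcov(fit), error = function(e)
    matrix(NA_real_, length(p), length(p)))
  se_log <- sqrt(pmax(diag(vc), 0))
  coefs <- c(k_tet = mod$k_tet, k_di = mod$k_di, L0 = mod$L0)
  ses <- c(k_tet = mod$k_tet * log(10) * se_log[1],
           k_di = mod$k_di * log(10) * se_log[2],
           L0 = if (float_L0) mod$L0 * log(10) * se_log[3] else 0)
  res <- log_L_model(mod, pH) - y
  structure(list(model = mod, coefficients = coefs, se = ses,
                 residuals = res, used = use, data = data,
                 rmsd = sqrt(mean(res[use]^2)),
                 converged = fit$info %in% 1:4, message = fit$message,
                 fixed_L0 = !float_L0),
            class = "linkage_fit")
}

#' @export
print.linkage_fit <- function(x, ...) {
  cat("pH-linkage fit of log10(L_obs)\n")
  cat(sprintf("  k_tet = %.3g +/- %.2g M^-1 (m = %d%s)\n",
              x$coefficients["k_tet"], x$se["k_tet"], x$model$m,
              if (x$model$coop_tet) ", cooperative" else ""))
  cat(sprintf("  k_di  = %.3g +/- %.2g M^-1 (n = %d%s)\n",
              x$coefficients["k_di"], x$se["k_di"], x$model$n,
              if (x$model$coop_di) ", cooperative" else ""))
  cat(sprintf("  L0    = %.3g M^-1%s\n", x$coefficients["L0"],
              if (x$fixed_L0) " (fixed normalization)" else ""))
  cat(sprintf("  RMSD  = %.3g log10 units over %d points\n",
              x$rmsd, sum(x$used)))
  if (!x$converged) cat("  WARNING: optimizer did not report convergence\n")
  invisible(x)
}

#' @export
coef.linkage_fit <- function(object, ...) object$coefficients

#' @export
residuals.linkage_fit <- function(object, ...) object$residuals

#' @export
predict.linkage_fit <- function(object, pH, ...) {
  predict(object$model, pH, ...)
}

#' @export
summary.linkage_fit <- function(object, ...) {
  print(object)
  cat("\nPer-point residuals (log10 units):\n")
  print(data.frame(pH = object$data$pH, residual = object$residuals,
                   used = object$used))
  invisible(object)
}

#' @export
plot.linkage_fit <- function(x, ...) {
  d <- x$data
  grid <- seq(min(d$pH) - 0.3, max(d$pH) + 0.3, length.out = 200)
  graphics::plot(d$pH, log10(d$L_obs),
                 pch = ifelse(x$used, 19, 1),
                 xlab = "pH", ylab = expression(log[10] ~ L[obs]), ...)
  graphics::lines(grid, log_L_model(x$model, grid))
  invisible(x)
}

#' Rank alternative protonation-site models on a (pH, L_obs) series
#'
#' Fits every supplied `(m, n, coop_tet, coop_di)` variant with
#' [fit_linkage] and returns a table ranked by RMSD on the log scale.
#'
#' @param data As in [fit_linkage].
#' @param variants Data frame with columns `m`, `n`, `coop_tet`, `coop_di`;
#'   the default crosses cooperative/independent at `m = 3`, `n = 2`.
#' @param ... Passed to [fit_linkage].
#' @return Data frame of variants with `rmsd`, ranked best-first.
#' @export
compare_linkage_models <- function(data,
                                   variants = expand.grid(
                                     m = 3, n = 2,
                                     coop_tet = c(TRUE, FALSE),
                                     coop_di = c(TRUE, FALSE)),
                                   ...) {
  variants$rmsd <- vapply(seq_len(nrow(variants)), function(i) {
    f <- tryCatch(fit_linkage(data, m = variants$m[i], n = variants$n[i],
                              coop_tet = variants$coop_tet[i],
                              coop_di = variants$coop_di[i], ...),
                  error = function(e) NULL)
    if (is.null(f)) NA_real_ else f$rmsd
  }, 0)
  variants[order(variants$rmsd), ]
}
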