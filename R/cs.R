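# Regularized sedimentation-coefficient distributions.
#
# Velocity scans are decomposed on a grid of non-interacting single-species
# Lamm solutions; amplitudes are obtained by nonnegative least squares with
# a second-difference (Tikhonov) smoothness penalty. This is a deliberately
# simplified c(s) analysis: the frictional-ratio parameter maps each s to a
# diffusion coefficient, and the regularization weight is fixed by the user
# rather than selected by an F test.

# diffusion coefficient implied by (s, f/f0, vbar) in a given buffer:
# f0 = 6 pi eta R0, R0 = (3 M vbar / 4 pi Na)^(1/3), s = M(1-vbar rho)/(Na f)
#' @noRd
cs_diffusion <- function(s_svedberg, f_ratio, vbar, buffer) {
  eta <- buffer$viscosity * 0.01        # cP -> poise
  rho <- buffer$density
  b <- 1 - vbar * rho
  stopifnot(b > 0)
  s_sec <- s_svedberg * .SVEDBERG
  m23 <- s_sec * .NAVO * f_ratio * 6 * pi * eta *
    (3 * vbar / (4 * pi * .NAVO))^(1 / 3) / b
  M <- m23^(3 / 2)                      # g/mol
  s_sec * .RGAS_CGS * buffer$temperature / (M * b)
}

# Lawson-Hanson nonnegative least squares (no NNLS solver ships with the
# pre-set dependency stack, so it is implemented here)
#' @noRd
nnls_lh <- function(A, b, tol = NULL, max_iter = NULL) {
  n <- ncol(A)
  if (is.null(max_iter)) max_iter <- 5 * n
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- crossprod(A, b - A %*% x)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * sum(abs(A)) * nrow(A)
  iter <- 0
  while (any(!passive) && any(w[!passive] > tol) && iter < max_iter) {
    iter <- iter + 1
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      idx <- which(passive)
      zi <- qr.coef(qr(A[, idx, drop = FALSE]), b)
      zi[is.na(zi)] <- 0
      z[idx] <- zi
      if (all(z[idx] > 0)) break
      neg <- passive & z <= 0
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive <- passive & x > .Machine$double.eps
    }
    x <- z
    w <- crossprod(A, b - A %*% x)
  }
  as.numeric(x)
}

#' Fit a regularized sedimentation-coefficient distribution
#'
#' Builds single-species Lamm basis functions on a grid of sedimentation
#' coefficients (diffusion tied to `s` through the frictional ratio), and
#' resolves the scan set on that basis by nonnegative least squares with a
#' second-difference smoothness penalty.
#'
#' @param scans An `sv_scanset` (at least 10 scans spanning boundary
#'   movement).
#' @param s_grid Grid of sedimentation coefficients, Svedberg.
#' @param f_ratio Frictional ratio f/f0 shared by the grid.
#' @param vbar Partial specific volume assumed for the grid, ml/g.
#' @param alpha Regularization weight (relative; 0 disables smoothing).
#' @param optimize_f_ratio If `TRUE`, the frictional ratio is optimized by a
#'   coarse-then-fine grid search minimizing the fit RMSD (the usual
#'   practice); `f_ratio` is then the search center.
#' @param r_exclude Fractions of the column excluded near the meniscus and
#'   bottom (back-diffusion pile-up), default `c(0.02, 0.12)`.
#' @param radial_stride Keep every k-th radial point (default targets about
#'   120 points).
#' @param time_stride Keep every k-th scan (default 1).
#' @param dt_basis Time step for the basis simulations, s.
#' @return An object of class `"cs_fit"`: `s`, `c_of_s` (AU/S), grid
#'   amplitudes, per-scan RMSD and the fit configuration.
#' @export
fit_cs <- function(scans, s_grid = seq(0.3, 4, length.out = 75),
                   f_ratio = 1.5, vbar = 0.72, alpha = 0.1,
                   r_exclude = c(0.02, 0.12), radial_stride = NULL,
                   time_stride = 1, dt_basis = 5,
                   optimize_f_ratio = FALSE) {
  stopifnot(inherits(scans, "sv_scanset"), length(scans$times) >= 10,
            all(diff(s_grid) > 0))
  if (optimize_f_ratio) {
    one <- function(fr) fit_cs(scans, s_grid, fr, vbar, alpha, r_exclude,
                               radial_stride, time_stride, dt_basis,
                               optimize_f_ratio = FALSE)
    coarse <- seq(1.2, 2.1, by = 0.3)
    fits <- lapply(coarse, one)
    i <- which.min(vapply(fits, function(f) f$rmsd, 0))
    fine <- coarse[i] + c(-0.15, 0.15)
    fits2 <- lapply(fine, one)
    all_f <- c(fits, fits2)
    return(all_f[[which.min(vapply(all_f, function(f) f$rmsd, 0))]])
  }
  g <- scans$geometry
  r <- scans$radii
  col <- g$bottom - g$meniscus
  keep_r <- r >= g$meniscus + r_exclude[1] * col &
    r <= g$bottom - r_exclude[2] * col
  if (is.null(radial_stride))
    radial_stride <- max(1L, floor(sum(keep_r) / 120))
  idx_r <- which(keep_r)[seq(1, sum(keep_r), by = radial_stride)]
  idx_t <- seq(1, length(scans$times), by = time_stride)
  b_vec <- as.numeric(scans$absorbance[idx_t, idx_r])

  if (all(abs(b_vec) < 1e-12)) {
    return(structure(list(s = s_grid,
                          c_of_s = numeric(length(s_grid)),
                          amplitudes = numeric(length(s_grid)),
                          rmsd = 0, alpha = alpha, f_ratio = f_ratio,
                          vbar = vbar, scans = scans),
                     class = "cs_fit"))
  }

  A <- matrix(0, length(b_vec), length(s_grid))
  for (j in seq_along(s_grid)) {
    D <- cs_diffusion(s_grid[j], f_ratio, vbar, scans$buffer)
    sim <- simulate_lamm_single(s_grid[j], D, g, scans$times[idx_t],
                                loading = 1, dt = dt_basis)
    A[, j] <- as.numeric(sim$profiles[, idx_r])
  }

  if (alpha > 0 && length(s_grid) > 2) {
    ns <- length(s_grid)
    D2 <- diag(ns)[-c(1, ns), , drop = FALSE] * 0
    for (i in seq_len(ns - 2)) D2[i, i:(i + 2)] <- c(1, -2, 1)
    lam <- alpha * sqrt(sum(A^2) / sum(D2^2))
    Aaug <- rbind(A, lam * D2)
    baug <- c(b_vec, numeric(nrow(D2)))
  } else {
    Aaug <- A
    baug <- b_vec
  }
  x <- nnls_lh(Aaug, baug)
  fit_vec <- as.numeric(A %*% x)
  ds <- mean(diff(s_grid))
  structure(list(s = s_grid, c_of_s = x / ds, amplitudes = x,
                 rmsd = sqrt(mean((fit_vec - b_vec)^2)),
                 alpha = alpha, f_ratio = f_ratio, vbar = vbar,
                 scans = scans),
            class = "cs_fit")
}

#' @export
print.cs_fit <- function(x, ...) {
  cat(sprintf("c(s) distribution: %d grid points in [%.2f, %.2f] S, RMSD %.4g AU\n",
              length(x$s), min(x$s), max(x$s), x$rmsd))
  pk <- cs_peaks(x)
  if (nrow(pk)) {
    cat("  peaks:\n")
    for (i in seq_len(nrow(pk)))
      cat(sprintf("    %.2f S (height %.3g AU/S)\n", pk$s[i], pk$height[i]))
  }
  invisible(x)
}

#' @export
plot.cs_fit <- function(x, ...) {
  graphics::plot(x$s, x$c_of_s, type = "l", xlab = "s (S)",
                 ylab = "c(s) (AU/S)", ...)
  invisible(x)
}

#' Local maxima of a c(s) distribution
#'
#' @param fit A `cs_fit`.
#' @param min_height_frac Peaks below this fraction of the tallest peak are
#'   dropped.
#' @return Data frame with peak `s`, `height` and the integrated signal of
#'   the contiguous region around each peak.
#' @export
cs_peaks <- function(fit, min_height_frac = 0.05) {
  stopifnot(inherits(fit, "cs_fit"))
  cc <- fit$c_of_s
  n <- length(cc)
  if (max(cc) <= 0)
    return(data.frame(s = numeric(0), height = numeric(0),
                      area = numeric(0)))
  is_pk <- which(cc > c(-Inf, cc[-n]) & cc >= c(cc[-1], -Inf) &
                   cc > min_height_frac * max(cc))
  ds <- mean(diff(fit$s))
  area <- vapply(is_pk, function(i) {
    lo <- i; while (lo > 1 && cc[lo - 1] > 0.02 * cc[i]) lo <- lo - 1
    hi <- i; while (hi < n && cc[hi + 1] > 0.02 * cc[i]) hi <- hi + 1
    sum(cc[lo:hi]) * ds
  }, 0)
  data.frame(s = fit$s[is_pk], height = cc[is_pk], area = area)
}

#' Weight-average sedimentation coefficient from a c(s) distribution
#'
#' `s_w = integral(s c(s) ds) / integral(c(s) ds)` over the requested range.
#'
#' @param fit A `cs_fit`.
#' @param range `c(smin, smax)` in Svedberg; default the full grid.
#' @return Weight-average s, Svedberg.
#' @export
weight_average_s <- function(fit, range = NULL) {
  stopifnot(inherits(fit, "cs_fit"))
  if (is.null(range)) range <- range(fit$s)
  sel <- fit$s >= range[1] & fit$s <= range[2]
  tot <- sum(fit$c_of_s[sel])
  if (!any(sel) || tot <= 0)
    stop("no signal mass in the requested s range")
  sum(fit$s[sel] * fit$c_of_s[sel]) / tot
}
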