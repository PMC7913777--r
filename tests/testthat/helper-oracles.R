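# Independent oracles and small fixture builders shared across tests.

# trapezoidal sector integral, written independently of the package
trapz_r <- function(r, a) sum(diff(r) * (a[-1] * r[-1] + a[-length(a)] * r[-length(r)]) / 2)

# brute-force free-ligand solve by bisection on the mass balance
free_ligand_bisect <- function(X_tot, M_tot, n, K, iters = 200) {
  f <- function(x) x + n * K * x / (1 + K * x) * M_tot - X_tot
  lo <- 0; hi <- X_tot
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# brute-force equilibrium of the six-species network: bisection over free O,
# nested with the closed-form dimer quadratic on the R balance
equilibrium_bisect <- function(O_total, R_total, K, iters = 200) {
  L <- K[1]; K2 <- K[2]; K3 <- K[3]; K4 <- K[4]
  ydim <- function(x) {
    a <- 4 * L * (1 + K3 * x + K3 * K4 * x^2)
    b <- 2 * (1 + K2 * x)
    if (a == 0) R_total / b else (-b + sqrt(b^2 + 4 * a * R_total)) / (2 * a)
  }
  obal <- function(x) {
    y <- ydim(x)
    x + K2 * x * y + K3 * L * x * y^2 + 2 * K3 * K4 * L * x^2 * y^2 - O_total
  }
  lo <- 0; hi <- O_total
  if (O_total == 0 || obal(hi) <= 0) {
    x <- O_total
  } else {
    for (i in seq_len(iters)) {
      mid <- (lo + hi) / 2
      if (obal(mid) > 0) hi <- mid else lo <- mid
    }
    x <- (lo + hi) / 2
  }
  y <- ydim(x)
  c(O = x, R2 = y, R4 = L * y^2, R2O = K2 * x * y,
    R4O = K3 * x * L * y^2, R4O2 = K3 * K4 * x^2 * L * y^2)
}

# reference radial exponent computed from first principles (CGS)
sigma_oracle <- function(M_kDa, vbar, rho, rpm, T = 298.15) {
  omega <- rpm * 2 * pi / 60
  M_kDa * 1000 * (1 - vbar * rho) * omega^2 / (2 * 8.314462618e7 * T)
}

# mass-conserving reference amplitude: A at r0 = meniscus such that the
# sector-average of A0 exp(sigma (r^2 - r0^2)) equals `loading`
conserved_amplitude <- function(loading, sigma, meniscus, bottom) {
  r <- seq(meniscus, bottom, length.out = 2001)
  prof <- exp(sigma * (r^2 - meniscus^2))
  loading * (bottom^2 - meniscus^2) / 2 / trapz_r(r, prof)
}

# wrap a plain profile matrix as an sv_scanset
as_scanset <- function(radii, times, absorbance, geometry, buffer) {
  structure(list(radii = radii, times = times, absorbance = absorbance,
                 geometry = geometry, buffer = buffer, noise_sd = 0),
            class = "sv_scanset")
}
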