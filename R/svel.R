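# Sedimentation velocity of a reacting system: the six-species RecO/RecR
# assembly network, its equilibrium speciation and kinetic fluxes, and a
# finite-volume reaction-coupled Lamm-equation solver.
#
# Network (four reversible reactions, acyclic):
#   2 R2        <-> R4       L_obs = [R4]/[R2]^2
#   R2  + O     <-> R2O      K2
#   R4  + O     <-> R4O      K3
#   R4O + O     <-> R4O2     K4
# Forward rate constants are K * k_off for each reaction.

.SV_SPECIES <- c("O", "R2", "R4", "R2O", "R4O", "R4O2")

# stoichiometry matrix, species x reactions
.SV_NU <- matrix(c(
  #  r1: 2R2->R4  r2: R2+O->R2O  r3: R4+O->R4O  r4: R4O+O->R4O2
  0, -1, -1, -1,    # O
  -2, -1,  0,  0,   # R2
  1,  0, -1,  0,    # R4
  0,  1,  0,  0,    # R2O
  0,  0,  1, -1,    # R4O
  0,  0,  0,  1     # R4O2
), nrow = 6, byrow = TRUE,
dimnames = list(.SV_SPECIES, paste0("r", 1:4)))

# monomer-content rows: totals conserved by every reaction
.SV_O_CONTENT <- c(1, 0, 0, 1, 1, 2)
.SV_R_CONTENT <- c(0, 2, 4, 2, 4, 4)   # RecR monomers

#' Default hydrodynamic table of the RecO/RecR assembly species
#'
#' Sedimentation coefficients (Svedberg, working buffer), molar masses (kDa),
#' additivity partial specific volumes (ml/g) and 230 nm extinction
#' coefficients (M^-1 cm^-1; 1.55e5 per RecO monomer, 5.3e4 per RecR
#' monomer) for the six species of the assembly network.
#'
#' @return Data frame with one row per species.
#' @export
scheme_species_table <- function() {
  eo <- 1.55e5
  er <- 5.3e4
  data.frame(
    name = .SV_SPECIES,
    molar_mass = c(27.4, 43.9, 87.8, 71.3, 115.2, 142.6),
    vbar = c(0.734, 0.711, 0.711, 0.720, 0.716, 0.720),
    s = c(0.8, 1.2, 1.7, 1.4, 1.9, 2.5),
    extinction = c(eo, 2 * er, 4 * er, 2 * er + eo, 4 * er + eo,
                   4 * er + 2 * eo))
}

#' Reaction network of RecO binding to self-associating RecR
#'
#' @param L_obs Tetramerization constant `[R4]/[R2]^2`, M^-1.
#' @param K2 RecO-dimer association constant, M^-1 (fixed low by default
#'   because the R2O species is not observed at equilibrium).
#' @param K3 First RecO-tetramer association constant, M^-1.
#' @param K4 Second RecO-tetramer association constant, M^-1.
#' @param k_off Reverse rate constant(s), s^-1; scalar or one per reaction.
#' @param species Hydrodynamic species table; see [scheme_species_table].
#' @param statistical_factors If `TRUE`, the supplied `K3`/`K4` are treated
#'   as intrinsic site constants and converted to macroscopic step-wise
#'   constants (`2 K3`, `K4 / 2`) before building rate constants.
#' @return An object of class `"reaction_network"`.
#' @export
reaction_network <- function(L_obs, K2 = 10, K3, K4, k_off = 0.01,
                             species = scheme_species_table(),
                             statistical_factors = FALSE) {
  stopifnot(L_obs >= 0, K2 >= 0, K3 >= 0, K4 >= 0, all(k_off > 0))
  if (length(k_off) == 1) k_off <- rep(k_off, 4)
  stopifnot(length(k_off) == 4)
  Keff <- c(L_obs, K2,
            if (statistical_factors) 2 * K3 else K3,
            if (statistical_factors) K4 / 2 else K4)
  structure(list(K = c(L_obs = L_obs, K2 = K2, K3 = K3, K4 = K4),
                 K_eff = Keff, k_off = k_off, k_on = Keff * k_off,
                 species = species,
                 statistical_factors = statistical_factors),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("reaction network: 2R2<->R4, R2+O<->R2O, R4+O<->R4O, R4O+O<->R4O2\n")
  cat(sprintf("  L_obs = %.3g, K2 = %.3g, K3 = %.3g, K4 = %.3g M^-1\n",
              x$K[1], x$K[2], x$K[3], x$K[4]))
  cat(sprintf("  k_off = %s s^-1%s\n",
              paste(format(x$k_off), collapse = ", "),
              if (x$statistical_factors) " (statistical factors applied)" else ""))
  invisible(x)
}

#' Mass-action reaction rates (one-way net rate per reaction)
#' @noRd
reaction_rates <- function(conc, network) {
  kf <- network$k_on; kr <- network$k_off
  c(kf[1] * conc[2]^2 - kr[1] * conc[3],
    kf[2] * conc[1] * conc[2] - kr[2] * conc[4],
    kf[3] * conc[1] * conc[3] - kr[3] * conc[5],
    kf[4] * conc[1] * conc[5] - kr[4] * conc[6])
}

#' Reaction contribution to d(concentration)/dt
#'
#' @param conc Named or ordered concentrations of (O, R2, R4, R2O, R4O,
#'   R4O2), M.
#' @param network A [reaction_network].
#' @return Rate of change of each species from reactions alone, M/s. The
#'   total O and total R monomer contents are conserved exactly.
#' @export
reaction_fluxes <- function(conc, network) {
  stopifnot(length(conc) == 6, all(is.finite(conc)))
  drop(.SV_NU %*% reaction_rates(conc, network))
}

#' Equilibrium composition of the assembly network
#'
#' Solves the coupled mass-action/mass-balance system for given total RecO
#' and total RecR (monomer) concentrations: for a trial free-O concentration
#' the RecR balance is a quadratic in free dimer, and the O balance is then
#' monotone in free O and solved by safeguarded root bracketing.
#'
#' @param O_total Total RecO, M.
#' @param R_total Total RecR in monomer units, M.
#' @param network A [reaction_network].
#' @param tol Relative conservation tolerance demanded of the solution.
#' @return Named vector of the six species concentrations, M.
#' @export
equilibrium_composition <- function(O_total, R_total, network,
                                    tol = 1e-10) {
  stopifnot(O_total >= 0, R_total >= 0)
  K <- unname(network$K)
  L <- K[1]; K2 <- K[2]; K3 <- K[3]; K4 <- K[4]

  free_dimer <- function(x) {
    a <- 4 * L * (1 + K3 * x + K3 * K4 * x^2)
    b <- 2 * (1 + K2 * x)
    if (R_total == 0) return(0)
    if (a == 0) return(R_total / b)
    # positive root of a y^2 + b y - R_total = 0, written stably
    2 * R_total / (b + sqrt(b^2 + 4 * a * R_total))
  }
  o_balance <- function(x) {
    y <- free_dimer(x)
    x * (1 + K2 * y + K3 * L * y^2 + 2 * K3 * K4 * L * x * y^2) - O_total
  }

  if (O_total == 0) {
    x <- 0
  } else if (o_balance(O_total) <= 0) {
    x <- O_total   # no binding
  } else {
    x <- stats::uniroot(o_balance, c(0, O_total),
                        tol = O_total * 1e-15)$root
    # Newton polish
    for (i in 1:3) {
      h <- max(x * 1e-7, 1e-30)
      g <- o_balance(x)
      dg <- (o_balance(x + h) - g) / h
      if (is.finite(dg) && dg > 0) x <- max(x - g / dg, 0)
    }
  }
  y <- free_dimer(x)
  out <- c(O = x, R2 = y, R4 = L * y^2, R2O = K2 * x * y,
           R4O = K3 * x * L * y^2, R4O2 = K3 * K4 * x^2 * L * y^2)
  oc <- sum(.SV_O_CONTENT * out)
  rc <- sum(.SV_R_CONTENT * out)
  if (O_total > 0 && abs(oc - O_total) > tol * O_total)
    stop("equilibrium solve failed O conservation: ", oc, " vs ", O_total)
  if (R_total > 0 && abs(rc - R_total) > tol * R_total)
    stop("equilibrium solve failed R conservation: ", rc, " vs ", R_total)
  out
}

#' Centrifuge cell geometry for velocity simulations
#'
#' @param meniscus,bottom Cell limits, cm.
#' @param rotor_speed Rotor speed, rpm.
#' @param pathlength Optical pathlength, cm.
#' @param n_points Number of radial cells (>= 100).
#' @return An object of class `"cell_geometry"`.
#' @export
cell_geometry <- function(meniscus = 6.14, bottom = 7.2,
                          rotor_speed = 42000, pathlength = 1.2,
                          n_points = 400) {
  stopifnot(meniscus < bottom, n_points >= 100, rotor_speed >= 0,
            pathlength > 0)
  structure(list(meniscus = meniscus, bottom = bottom,
                 rotor_speed = rotor_speed, pathlength = pathlength,
                 n_points = as.integer(n_points)),
            class = "cell_geometry")
}

# Bernoulli function B(x) = x / (e^x - 1), the exponential-fitting weight
#' @noRd
bernoulli_B <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-10
  out[small] <- 1 - x[small] / 2
  big <- x > 700
  out[big] <- 0
  ok <- !small & !big
  out[ok] <- x[ok] / expm1(x[ok])
  out
}

# Finite-volume Lamm transport operator with Scharfetter-Gummel fluxes.
# Returns the tridiagonal rate matrix T (dc/dt = T c) as a sparse matrix.
#' @noRd
lamm_operator <- function(s_sec, D, geometry) {
  n <- geometry$n_points
  dr <- (geometry$bottom - geometry$meniscus) / n
  rc <- geometry$meniscus + (seq_len(n) - 0.5) * dr
  rf <- geometry$meniscus + seq_len(n - 1) * dr     # interior faces
  omega <- rpm_to_omega(geometry$rotor_speed)
  v <- s_sec * omega^2 * rf                          # face velocities, cm/s
  if (D > 0) {
    pe <- v * dr / D
    alpha <- rf * (D / dr) * bernoulli_B(-pe)        # coeff on left cell
    beta <- rf * (D / dr) * bernoulli_B(pe)          # coeff on right cell
  } else {
    alpha <- rf * pmax(v, 0)
    beta <- rf * pmax(-v, 0)
  }
  # F_k = alpha_k c_k - beta_k c_{k+1};  dc_j/dt = -(F_j - F_{j-1})/(r_j dr)
  w <- 1 / (rc * dr)
  diag_main <- numeric(n)
  diag_main[1:(n - 1)] <- diag_main[1:(n - 1)] - alpha * w[1:(n - 1)]
  diag_main[2:n] <- diag_main[2:n] - beta * w[2:n]
  upper <- beta * w[1:(n - 1)]
  lower <- alpha * w[2:n]
  Matrix::bandSparse(n, n, k = -1:1,
                     diagonals = list(lower, diag_main, upper))
}

# theta-scheme stepper with prefactored sparse LU
#' @noRd
make_stepper <- function(Tmat, dt, theta = 0.5) {
  n <- nrow(Tmat)
  I <- Matrix::Diagonal(n)
  A <- I - theta * dt * Tmat
  B <- I + (1 - theta) * dt * Tmat
  lu <- Matrix::lu(A)
  function(c0) as.numeric(Matrix::solve(lu, B %*% c0))
}

# One linearized L-stable (Rosenbrock-Euler) reaction step applied to all
# cells at once: c <- c + dt * nu (R + dt z), (I4 - dt A) z = A R with the
# 4x4 capacity matrix A = W nu solved by unrolled Gaussian elimination on
# cell-vectors. Conserves monomer totals exactly (rows of nu).
#' @noRd
reaction_step <- function(conc, network, dt) {
  kf <- network$k_on; kr <- network$k_off
  c1 <- conc[, 1]; c2 <- conc[, 2]; c3 <- conc[, 3]
  c5 <- conc[, 5]; c6 <- conc[, 6]; c4 <- conc[, 4]
  R1 <- kf[1] * c2^2 - kr[1] * c3
  R2 <- kf[2] * c1 * c2 - kr[2] * c4
  R3 <- kf[3] * c1 * c3 - kr[3] * c5
  R4 <- kf[4] * c1 * c5 - kr[4] * c6
  # capacity matrix A = W nu (4x4 per cell)
  a11 <- -4 * kf[1] * c2 - kr[1]; a12 <- -2 * kf[1] * c2
  a13 <- kr[1];                   a14 <- 0
  a21 <- -2 * kf[2] * c1
  a22 <- -kf[2] * (c1 + c2) - kr[2]
  a23 <- -kf[2] * c2;             a24 <- -kf[2] * c2
  a31 <- kf[3] * c1;              a32 <- -kf[3] * c3
  a33 <- -kf[3] * (c1 + c3) - kr[3]
  a34 <- -kf[3] * c3 + kr[3]
  a41 <- 0;                       a42 <- -kf[4] * c5
  a43 <- kf[4] * (c1 - c5)
  a44 <- -kf[4] * (c1 + c5) - kr[4]
  b1 <- a11 * R1 + a12 * R2 + a13 * R3 + a14 * R4
  b2 <- a21 * R1 + a22 * R2 + a23 * R3 + a24 * R4
  b3 <- a31 * R1 + a32 * R2 + a33 * R3 + a34 * R4
  b4 <- a41 * R1 + a42 * R2 + a43 * R3 + a44 * R4
  # M = I - dt A
  m11 <- 1 - dt * a11; m12 <- -dt * a12; m13 <- -dt * a13; m14 <- -dt * a14
  m21 <- -dt * a21; m22 <- 1 - dt * a22; m23 <- -dt * a23; m24 <- -dt * a24
  m31 <- -dt * a31; m32 <- -dt * a32; m33 <- 1 - dt * a33; m34 <- -dt * a34
  m41 <- -dt * a41; m42 <- -dt * a42; m43 <- -dt * a43; m44 <- 1 - dt * a44
  # forward elimination (diagonals are >= 1, no pivoting needed)
  f <- m21 / m11
  m22 <- m22 - f * m12; m23 <- m23 - f * m13; m24 <- m24 - f * m14
  b2 <- b2 - f * b1
  f <- m31 / m11
  m32 <- m32 - f * m12; m33 <- m33 - f * m13; m34 <- m34 - f * m14
  b3 <- b3 - f * b1
  f <- m41 / m11
  m42 <- m42 - f * m12; m43 <- m43 - f * m13; m44 <- m44 - f * m14
  b4 <- b4 - f * b1
  f <- m32 / m22
  m33 <- m33 - f * m23; m34 <- m34 - f * m24; b3 <- b3 - f * b2
  f <- m42 / m22
  m43 <- m43 - f * m23; m44 <- m44 - f * m24; b4 <- b4 - f * b2
  f <- m43 / m33
  m44 <- m44 - f * m34; b4 <- b4 - f * b3
  z4 <- b4 / m44
  z3 <- (b3 - m34 * z4) / m33
  z2 <- (b2 - m23 * z3 - m24 * z4) / m22
  z1 <- (b1 - m12 * z2 - m13 * z3 - m14 * z4) / m11
  g1 <- R1 + dt * z1; g2 <- R2 + dt * z2
  g3 <- R3 + dt * z3; g4 <- R4 + dt * z4
  conc[, 1] <- c1 + dt * (-g2 - g3 - g4)
  conc[, 2] <- c2 + dt * (-2 * g1 - g2)
  conc[, 3] <- c3 + dt * (g1 - g3)
  conc[, 4] <- c4 + dt * g2
  conc[, 5] <- c5 + dt * (g3 - g4)
  conc[, 6] <- c6 + dt * g4
  conc
}

#' Simulate sedimentation velocity of the reacting system
#'
#' Solves the reaction-coupled Lamm equations on a finite-volume radial grid
#' with exponential-fitting (Scharfetter-Gummel) fluxes, zero-flux walls,
#' theta-scheme transport with prefactored sparse LU per species, and an
#' L-stable linearized reaction substep (Strang splitting). The initial
#' condition is the uniform equilibrium composition of the loading mixture.
#'
#' @param network A [reaction_network]; per-species diffusion coefficients
#'   are derived from their sedimentation coefficients with
#'   [diffusion_from_s].
#' @param totals Named vector `c(O = , R = )`: total RecO and total RecR
#'   (monomers), M.
#' @param geometry A [cell_geometry].
#' @param times Output times, s (increasing, within 0-7200).
#' @param buffer A [buffer_state].
#' @param dt Transport time step, s. Halved automatically (up to 4 times)
#'   if monomer totals drift by more than 0.1 % over the run.
#' @param theta Implicitness of the transport step (0.5 = Crank-Nicolson).
#' @param reaction_substeps Reaction substeps per transport half-step.
#' @return An object of class `"sv_scanset"`: `radii` (cell centers, cm),
#'   `times`, `absorbance` (time x radius matrix, AU),
#'   `conc` (time x radius x species array, M), `geometry`, `buffer`,
#'   `network`, `noise_sd`.
#' @export
simulate_lamm <- function(network, totals, geometry, times, buffer,
                          dt = 2, theta = 0.5, reaction_substeps = 2) {
  stopifnot(inherits(network, "reaction_network"),
            inherits(geometry, "cell_geometry"),
            all(c("O", "R") %in% names(totals)),
            all(diff(times) > 0), times[1] >= 0,
            max(times) <= 7200)
  sp <- network$species
  for (attempt in 0:4) {
    out <- lamm_run(network, totals, geometry, times, buffer, dt, theta,
                    reaction_substeps)
    if (out$max_drift < 1e-3) break
    dt <- dt / 2
    if (attempt == 4)
      stop("mass conservation drift ", out$max_drift,
           " persists at dt = ", dt, " s")
  }
  structure(list(radii = out$radii, times = times,
                 absorbance = out$absorbance, conc = out$conc,
                 geometry = geometry, buffer = buffer, network = network,
                 noise_sd = 0, drift = out$max_drift, dt = dt),
            class = "sv_scanset")
}

#' @noRd
lamm_run <- function(network, totals, geometry, times, buffer, dt, theta,
                     reaction_substeps) {
  sp <- network$species
  n <- geometry$n_points
  dr <- (geometry$bottom - geometry$meniscus) / n
  rc <- geometry$meniscus + (seq_len(n) - 0.5) * dr
  ops <- lapply(seq_len(nrow(sp)), function(i) {
    D <- if (is.na(sp$s[i]) || sp$s[i] == 0) 0 else
      diffusion_from_s(sp$s[i], sp$molar_mass[i], sp$vbar[i], buffer)
    lamm_operator(sp$s[i] * .SVEDBERG, D, geometry)
  })
  h_fact <- dt
  steppers <- lapply(ops, make_stepper, dt = dt, theta = theta)
  c0 <- equilibrium_composition(totals[["O"]], totals[["R"]], network)
  conc <- matrix(rep(c0, each = n), nrow = n)
  nt <- length(times)
  conc_out <- array(NA_real_, c(nt, n, 6))
  w <- rc * dr
  tot0 <- c(sum(w * (conc %*% .SV_O_CONTENT)),
            sum(w * (conc %*% .SV_R_CONTENT)))
  max_drift <- 0
  t_now <- 0
  k_out <- 1
  while (k_out <= nt) {
    t_target <- times[k_out]
    nsteps <- max(1L, ceiling((t_target - t_now) / dt - 1e-9))
    h <- (t_target - t_now) / nsteps
    if (t_target > t_now) {
      if (abs(h - h_fact) > 1e-12 * max(h, h_fact)) {
        steppers <- lapply(ops, make_stepper, dt = h, theta = theta)
        h_fact <- h
      }
      for (step in seq_len(nsteps)) {
        hr <- (h / 2) / reaction_substeps
        for (j in seq_len(reaction_substeps))
          conc <- reaction_step(conc, network, hr)
        for (i in 1:6) conc[, i] <- steppers[[i]](conc[, i])
        for (j in seq_len(reaction_substeps))
          conc <- reaction_step(conc, network, hr)
      }
      t_now <- t_target
    }
    conc_out[k_out, , ] <- conc
    tot <- c(sum(w * (conc %*% .SV_O_CONTENT)),
             sum(w * (conc %*% .SV_R_CONTENT)))
    drift <- max(abs(tot - tot0) / pmax(tot0, 1e-300))
    max_drift <- max(max_drift, drift)
    k_out <- k_out + 1
  }
  eps <- sp$extinction
  absorb <- matrix(0, nt, n)
  for (i in 1:6)
    absorb <- absorb + geometry$pathlength * eps[i] * conc_out[, , i]
  list(radii = rc, absorbance = absorb, conc = conc_out,
       max_drift = max_drift)
}

#' Simulate a single non-reacting species (transport only)
#'
#' Same solver as [simulate_lamm] restricted to one species; used for the
#' c(s) basis functions and analytic-transport checks.
#'
#' @param s Sedimentation coefficient, Svedberg.
#' @param D Diffusion coefficient, cm^2/s (0 allowed).
#' @param geometry A [cell_geometry].
#' @param times Output times, s.
#' @param loading Initial uniform signal (any linear unit).
#' @param dt Time step, s.
#' @param theta Transport implicitness.
#' @return List with `radii` and `profiles` (time x radius matrix).
#' @export
simulate_lamm_single <- function(s, D, geometry, times, loading = 1,
                                 dt = 2, theta = 0.5) {
  stopifnot(inherits(geometry, "cell_geometry"), all(diff(times) > 0))
  n <- geometry$n_points
  dr <- (geometry$bottom - geometry$meniscus) / n
  rc <- geometry$meniscus + (seq_len(n) - 0.5) * dr
  stepper <- make_stepper(lamm_operator(s * .SVEDBERG, D, geometry),
                          dt, theta)
  cvec <- rep(loading, n)
  nt <- length(times)
  prof <- matrix(NA_real_, nt, n)
  t_now <- 0
  for (k in seq_len(nt)) {
    t_target <- times[k]
    if (t_target > t_now) {
      nsteps <- max(1L, ceiling((t_target - t_now) / dt - 1e-9))
      h <- (t_target - t_now) / nsteps
      if (abs(h - dt) > 1e-12 * dt) {
        stepper_h <- make_stepper(lamm_operator(s * .SVEDBERG, D, geometry),
                                  h, theta)
        for (step in seq_len(nsteps)) cvec <- stepper_h(cvec)
      } else {
        for (step in seq_len(nsteps)) cvec <- stepper(cvec)
      }
      t_now <- t_target
    }
    prof[k, ] <- cvec
  }
  list(radii = rc, profiles = prof)
}

#' @export
print.sv_scanset <- function(x, ...) {
  cat(sprintf("sv_scanset: %d scans x %d radii, %d rpm, t = %.0f..%.0f s%s\n",
              length(x$times), length(x$radii), x$geometry$rotor_speed,
              min(x$times), max(x$times),
              if (x$noise_sd > 0)
                sprintf(", noise SD %.3g AU", x$noise_sd) else ""))
  invisible(x)
}

#' Add seeded Gaussian noise to a scan set
#'
#' Each scan receives i.i.d. Gaussian noise from its own reproducible
#' substream of the seed, so draws for one scan are unaffected by how many
#' other scans exist.
#'
#' @param scans An `sv_scanset`.
#' @param sd Noise standard deviation, AU.
#' @param seed Integer seed.
#' @return The scan set with noisy `absorbance` (concentrations untouched).
#' @export
add_noise <- function(scans, sd, seed = 1) {
  stopifnot(inherits(scans, "sv_scanset"), sd >= 0)
  if (sd == 0) return(scans)
  nr <- length(scans$radii)
  for (k in seq_along(scans$times)) {
    scans$absorbance[k, ] <- scans$absorbance[k, ] +
      sd * with_substream_noise(seed, k, nr)
  }
  scans$noise_sd <- sd
  scans
}

#' Weight-average sedimentation coefficient by the transport method
#'
#' Model-free estimate from the rate of depletion of the sector integral
#' landward of a plateau radius:
#' `d/dt integral(m..rp) c r dr = -s_w omega^2 rp^2 c_p(t)`.
#'
#' @param scans An `sv_scanset`.
#' @param window Plateau window as fractions of the column
#'   (default `c(0.55, 0.8)`); the analysis radius is its upper edge.
#' @param min_plateau Minimum plateau signal (AU) for a scan pair to count.
#' @return Weight-average sedimentation coefficient, Svedberg.
#' @export
transport_sw <- function(scans, window = c(0.55, 0.8), min_plateau = 0.01) {
  stopifnot(inherits(scans, "sv_scanset"), length(scans$times) >= 2)
  g <- scans$geometry
  r <- scans$radii
  rp <- g$meniscus + window[2] * (g$bottom - g$meniscus)
  in_win <- r >= g$meniscus + window[1] * (g$bottom - g$meniscus) & r <= rp
  sel <- r <= rp
  omega <- rpm_to_omega(g$rotor_speed)
  # sector mass landward of the control surface; on the solver's uniform
  # grid the depletion of the cell-mass sum equals minus the flux through
  # the face just seaward of the last included cell, so the control radius
  # is that face, not rp itself
  dr <- stats::median(diff(r))
  rp <- max(r[sel]) + dr / 2
  integ <- function(a) sum(a[sel] * r[sel] * dr)
  I <- apply(scans$absorbance, 1, integ)
  cp <- apply(scans$absorbance[, in_win, drop = FALSE], 1, mean)
  # plateau must be flat: reject strongly sloped windows
  slope_ok <- apply(scans$absorbance[, in_win, drop = FALSE], 1, function(a)
    stats::sd(a) < 0.25 * max(mean(a), min_plateau))
  est <- c()
  for (k in seq_len(length(I) - 1)) {
    cbar <- (cp[k] + cp[k + 1]) / 2
    if (cbar < min_plateau || !slope_ok[k] || !slope_ok[k + 1]) next
    dtk <- scans$times[k + 1] - scans$times[k]
    est <- c(est, -(I[k + 1] - I[k]) / (dtk * omega^2 * rp^2 * cbar))
  }
  if (length(est) == 0)
    stop("no identifiable plateau in the requested window")
  mean(est) / .SVEDBERG
}
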