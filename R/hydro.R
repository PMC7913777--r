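# Composition bookkeeping and hydrodynamic conversions: molar masses,
# partial specific volumes, buoyant factors, diffusion coefficients and
# standard-condition corrections of sedimentation coefficients.

#' Define a sedimenting species
#'
#' A species is one sedimenting, absorbing molecular entity: a protomer or a
#' defined complex. If a `composition` table is supplied, the molar mass and
#' partial specific volume are checked against (or derived from) mass-weighted
#' additivity over the components.
#'
#' @param name Species label.
#' @param molar_mass Molar mass in kDa. May be omitted when `composition` is
#'   given, in which case it is the composition sum.
#' @param vbar Partial specific volume in ml/g. May be omitted when
#'   `composition` is given (mass-weighted mean is used).
#' @param s Sedimentation coefficient in Svedberg (1e-13 s) in the working
#'   buffer, or `NA` if unknown.
#' @param extinction Molar extinction coefficient (M^-1 cm^-1) at the working
#'   wavelength.
#' @param composition Optional data frame with columns `component`, `copies`,
#'   `molar_mass` (kDa) and `vbar` (ml/g) describing the monomer content.
#' @return An object of class `"species"`.
#' @examples
#' recO <- species("RecO", molar_mass = 27.4, vbar = 0.734,
#'                 s = 0.8, extinction = 1.55e5)
#' @export
species <- function(name, molar_mass = NULL, vbar = NULL, s = NA_real_,
                    extinction = 0, composition = NULL) {
  if (!is.null(composition)) {
    stopifnot(is.data.frame(composition),
              all(c("component", "copies", "molar_mass", "vbar") %in%
                    names(composition)))
    m_sum <- total_molar_mass(composition$copies, composition$molar_mass)
    v_sum <- vbar_additive(composition$copies, composition$molar_mass,
                           composition$vbar)
    if (is.null(molar_mass)) molar_mass <- m_sum
    if (is.null(vbar)) vbar <- v_sum
    if (abs(molar_mass - m_sum) > 0.05)
      stop("molar_mass (", molar_mass,
           " kDa) disagrees with composition sum (", m_sum, " kDa)")
  }
  if (is.null(molar_mass) || is.null(vbar))
    stop("molar_mass and vbar are required when no composition is given")
  if (!(molar_mass > 0)) stop("molar_mass must be positive")
  if (!(vbar > 0.5 && vbar < 1.0)) stop("vbar must lie in (0.5, 1.0) ml/g")
  if (extinction < 0) stop("extinction must be >= 0")
  structure(list(name = name, molar_mass = molar_mass, vbar = vbar,
                 s = s, extinction = extinction, composition = composition),
            class = "species")
}

#' @export
print.species <- function(x, ...) {
  cat(sprintf("species '%s': M = %.2f kDa, vbar = %.3f ml/g, s = %s S, eps = %g\n",
              x$name, x$molar_mass, x$vbar,
              ifelse(is.na(x$s), "?", format(x$s)), x$extinction))
  invisible(x)
}

#' Define a buffer state
#'
#' Solution conditions used by the hydrodynamic conversions: density,
#' viscosity, temperature and pH.
#'
#' @param density Solvent density, g/ml.
#' @param viscosity Solvent viscosity, cP.
#' @param temperature Absolute temperature, K.
#' @param pH Solution pH.
#' @param label Free-text description.
#' @return An object of class `"buffer_state"`.
#' @export
buffer_state <- function(density, viscosity, temperature = 298.15,
                         pH = 7.0, label = "") {
  stopifnot(density > 0, viscosity > 0,
            temperature > 273, temperature < 373,
            pH > 0, pH < 14)
  structure(list(density = density, viscosity = viscosity,
                 temperature = temperature, pH = pH, label = label),
            class = "buffer_state")
}

#' @export
print.buffer_state <- function(x, ...) {
  cat(sprintf("buffer '%s': rho = %.5f g/ml, eta = %.4f cP, T = %.2f K, pH %.2f\n",
              x$label, x$density, x$viscosity, x$temperature, x$pH))
  invisible(x)
}

#' Mass-weighted partial specific volume of a complex
#'
#' Computes the partial specific volume of a complex assuming additivity,
#' `vbar = sum(n_i M_i vbar_i) / sum(n_i M_i)`.
#'
#' @param moles Copy numbers (or mole amounts) of each component.
#' @param molar_mass Component molar masses, kDa.
#' @param vbar Component partial specific volumes, ml/g.
#' @return Partial specific volume of the complex, ml/g.
#' @examples
#' # one RecR tetramer + one RecO monomer
#' vbar_additive(c(4, 1), c(21.95, 27.4), c(0.711, 0.734))
#' @export
vbar_additive <- function(moles, molar_mass, vbar) {
  if (length(moles) == 0) stop("empty component list")
  stopifnot(length(molar_mass) == length(moles),
            length(vbar) == length(moles))
  if (any(moles <= 0) || any(molar_mass <= 0))
    stop("moles and molar masses must be positive")
  if (any(vbar <= 0.5) || any(vbar >= 1.0))
    stop("component vbar values must lie in (0.5, 1.0) ml/g")
  w <- moles * molar_mass
  sum(w * vbar) / sum(w)
}

#' Total molar mass of a complex
#'
#' @inheritParams vbar_additive
#' @return Total molar mass `sum(n_i M_i)`, kDa.
#' @examples
#' total_molar_mass(c(4, 2), c(21.95, 27.4))  # RecR4O2, 142.6 kDa
#' @export
total_molar_mass <- function(moles, molar_mass) {
  if (length(moles) == 0) stop("empty component list")
  stopifnot(length(molar_mass) == length(moles))
  if (any(moles <= 0) || any(molar_mass <= 0))
    stop("moles and molar masses must be positive")
  sum(moles * molar_mass)
}

#' Buoyant molar mass factor M(1 - vbar rho)
#'
#' @param molar_mass Molar mass, kDa.
#' @param vbar Partial specific volume, ml/g.
#' @param buffer A [buffer_state] supplying the density.
#' @return Buoyant factor in kDa.
#' @export
buoyant_factor <- function(molar_mass, vbar, buffer) {
  stopifnot(inherits(buffer, "buffer_state"), molar_mass > 0)
  molar_mass * (1 - vbar * buffer$density)
}

#' Diffusion coefficient from the Svedberg relation
#'
#' `D = s R T / (M (1 - vbar rho))`, the translational diffusion coefficient
#' implied by a sedimentation coefficient and a buoyant molar mass.
#'
#' @param s Sedimentation coefficient, Svedberg.
#' @param molar_mass Molar mass, kDa.
#' @param vbar Partial specific volume, ml/g.
#' @param buffer A [buffer_state].
#' @return Diffusion coefficient, cm^2/s.
#' @export
diffusion_from_s <- function(s, molar_mass, vbar, buffer) {
  mb <- buoyant_factor(molar_mass, vbar, buffer)   # kDa
  if (mb <= 0)
    stop("Svedberg relation undefined at neutral or negative buoyancy")
  # SI: s [s] * R [J/mol/K] * T / (M_b [kg/mol]) -> m^2/s; 1 m^2/s = 1e4 cm^2/s
  (s * .SVEDBERG) * .RGAS_SI * buffer$temperature / mb * 1e4
}

#' Correct a sedimentation coefficient to standard conditions (s20,w)
#'
#' Applies the standard viscosity/buoyancy correction
#' `s20w = s_obs * (eta_b / eta_20w) * (1 - vbar rho)_20w / (1 - vbar rho)_b`.
#' With `inverse = TRUE` the same factors are applied in reverse, mapping an
#' s20,w value back into the working buffer.
#'
#' @param s_obs Observed sedimentation coefficient, Svedberg.
#' @param buffer Working [buffer_state].
#' @param vbar Partial specific volume of the species, ml/g.
#' @param inverse Apply the inverse correction instead.
#' @return Corrected sedimentation coefficient, Svedberg.
#' @export
s20w_correct <- function(s_obs, buffer, vbar, inverse = FALSE) {
  stopifnot(inherits(buffer, "buffer_state"), vbar > 0.5, vbar < 1.0)
  b_buf <- 1 - vbar * buffer$density
  b_ref <- 1 - vbar * .RHO_20W
  if (b_buf <= 0 || b_ref <= 0)
    stop("neutral or negative buoyancy; correction undefined")
  fac <- (buffer$viscosity / .ETA_20W) * (b_ref / b_buf)
  if (inverse) s_obs / fac else s_obs * fac
}

# frozen glycerol-water property grid: rows are % v/v glycerol 0,5,...,50,
# columns are 15,20,25,30,35,40 C. Values were frozen from the Cheng (2008)
# viscosity mixing correlation and an apparent-specific-volume density model
# anchored to standard water density values; see the methods vignette.
.GLYC_VV <- seq(0, 50, 5)
.GLYC_TC <- c(15, 20, 25, 30, 35, 40)
.GLYC_RHO <- matrix(c(
  0.9991, 0.99821, 0.99705, 0.99565, 0.99404, 0.99222,
  1.0138, 1.01284, 1.01163, 1.01018, 1.00853, 1.00668,
  1.02847, 1.02744, 1.02617, 1.02468, 1.02299, 1.02111,
  1.0431, 1.04201, 1.04068, 1.03914, 1.03741, 1.03549,
  1.0577, 1.05654, 1.05515, 1.05356, 1.05179, 1.04984,
  1.07226, 1.07103, 1.06958, 1.06794, 1.06613, 1.06415,
  1.08679, 1.08548, 1.08397, 1.08228, 1.08043, 1.07842,
  1.10128, 1.09989, 1.09832, 1.09658, 1.09469, 1.09265,
  1.11573, 1.11427, 1.11264, 1.11084, 1.10891, 1.10684,
  1.13014, 1.12861, 1.12691, 1.12507, 1.12309, 1.12099,
  1.14452, 1.14291, 1.14114, 1.13925, 1.13723, 1.1351
), nrow = 11, byrow = TRUE)
.GLYC_ETA <- matrix(c(
  1.14135, 1.00486, 0.89274, 0.79951, 0.72114, 0.6546,
  1.33774, 1.17346, 1.03891, 0.92734, 0.83382, 0.75463,
  1.58423, 1.38333, 1.21946, 1.08411, 0.97106, 0.8757,
  1.8975, 1.64772, 1.44503, 1.27845, 1.13998, 1.02369,
  2.30115, 1.98517, 1.73039, 1.52227, 1.35025, 1.20656,
  2.82914, 2.42209, 2.09636, 1.83216, 1.61527, 1.43525,
  3.53131, 2.99677, 2.57278, 2.23173, 1.95391, 1.72501,
  4.48237, 3.76594, 3.2034, 2.75515, 2.39322, 2.09749,
  5.79694, 4.81547, 4.05359, 3.45294, 2.97277, 2.58407,
  7.65541, 6.27864, 5.22351, 4.40155, 3.75175, 3.23117,
  10.34989, 8.36804, 6.87071, 5.71966, 4.82091, 4.10919
), nrow = 11, byrow = TRUE)

#' @noRd
bilinear <- function(xg, yg, z, x, y) {
  i <- findInterval(x, xg, rightmost.closed = TRUE)
  j <- findInterval(y, yg, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(xg) - 1L)
  j <- min(max(j, 1L), length(yg) - 1L)
  tx <- (x - xg[i]) / (xg[i + 1] - xg[i])
  ty <- (y - yg[j]) / (yg[j + 1] - yg[j])
  (1 - tx) * (1 - ty) * z[i, j] + tx * (1 - ty) * z[i + 1, j] +
    (1 - tx) * ty * z[i, j + 1] + tx * ty * z[i + 1, j + 1]
}

#' Density and viscosity of glycerol-water buffers
#'
#' Bilinear interpolation of an embedded glycerol-water property grid
#' (0-50 % v/v, 15-40 C), with an optional linear molar density increment for
#' dissolved salt. Requests outside the tabulated range are an error; the
#' table is never extrapolated.
#'
#' @param glycerol_vv Glycerol concentration, percent v/v (0-50).
#' @param temperature Absolute temperature, K (288.15-313.15).
#' @param salt_molar Optional monovalent salt concentration, mol/l, applied as
#'   a linear density increment of 0.041 g ml^-1 M^-1; the (small) viscosity
#'   contribution of <= 200 mM salt is neglected.
#' @return A list with elements `density` (g/ml) and `viscosity` (cP).
#' @examples
#' glycerol_buffer_properties(25, 298.15)
#' @export
glycerol_buffer_properties <- function(glycerol_vv, temperature,
                                       salt_molar = 0) {
  tC <- temperature - 273.15
  if (glycerol_vv < 0 || glycerol_vv > 50)
    stop("glycerol_vv outside tabulated range [0, 50] % v/v")
  if (tC < 15 || tC > 40)
    stop("temperature outside tabulated range [288.15, 313.15] K")
  list(density = bilinear(.GLYC_VV, .GLYC_TC, .GLYC_RHO, glycerol_vv, tC) +
         0.041 * salt_molar,
       viscosity = bilinear(.GLYC_VV, .GLYC_TC, .GLYC_ETA, glycerol_vv, tC))
}

#' Working buffer of the RecOR study design
#'
#' The bis-tris-propane buffer with 25 % (v/v) glycerol used throughout the
#' synthetic experimental designs, with properties taken from
#' [glycerol_buffer_properties] at 25 C.
#'
#' @param pH Buffer pH (default 8.0).
#' @param temperature Absolute temperature, K.
#' @return A [buffer_state].
#' @export
btp_buffer <- function(pH = 8.0, temperature = 298.15) {
  p <- glycerol_buffer_properties(25, temperature)
  buffer_state(density = p$density, viscosity = p$viscosity,
               temperature = temperature, pH = pH,
               label = sprintf("BTP + 25%% glycerol, pH %.1f", pH))
}
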