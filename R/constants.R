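# Physical constants and reference solvent properties.
# One conversion layer: externally s is in Svedberg (1e-13 s), masses in kDa,
# radii in cm, densities in g/ml, viscosities in cP; internally CGS/SI as noted.

.RGAS_CGS <- 8.314462618e7   # erg mol^-1 K^-1 (g cm^2 s^-2 mol^-1 K^-1)
.RGAS_SI  <- 8.314462618     # J mol^-1 K^-1
.KBOLTZ   <- 1.380649e-16    # erg K^-1
.NAVO     <- 6.02214076e23   # mol^-1
.SVEDBERG <- 1e-13           # s

# water at 20 C, the s20,w reference state
.RHO_20W <- 0.99823          # g/ml
.ETA_20W <- 1.002            # cP

#' Reference water conditions (20 degrees C)
#'
#' Returns the fixed water-at-20-C reference state used for
#' standard-condition sedimentation coefficient corrections
#' (density 0.99823 g/ml, viscosity 1.002 cP).
#'
#' @return A [buffer_state] object.
#' @export
water_20C <- function() {
  buffer_state(density = .RHO_20W, viscosity = .ETA_20W,
               temperature = 293.15, pH = 7, label = "water, 20 C")
}

#' @noRd
rpm_to_omega <- function(rpm) rpm * 2 * pi / 60

#' @noRd
kda_to_gmol <- function(kda) kda * 1000
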