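# Electrokinetic conversions for rAAV particles: electrophoretic mobility
# to zeta potential (Smoluchowski, thin-double-layer limit) and to net
# charge via the Einstein relation with the measured diffusion coefficient.

.EPSILON0 <- 8.8541878128e-12   # vacuum permittivity, F/m
.KBOLTZ <- 1.380649e-23         # Boltzmann constant, J/K
.ECHARGE <- 1.602176634e-19     # elementary charge, C

#' Default solvent constants (water at 25 C)
#'
#' Viscosity 8.9e-4 Pa.s, relative permittivity 78.4, temperature
#' 298.15 K. Kept in one place so alternative solvents can be passed to
#' the conversions rather than edited into them.
#'
#' @return named list with `viscosity`, `relativePermittivity`,
#'   `temperature`
#' @export
solventDefaults <- function() {
  list(viscosity = 8.9e-4, relativePermittivity = 78.4,
       temperature = 298.15)
}

#' Zeta potential from electrophoretic mobility (Smoluchowski)
#'
#' `zeta = mu * eta / (eps0 * epsr)`, valid when the particle radius is
#' large compared to the Debye length; the sign follows the mobility sign.
#'
#' @param mobility electrophoretic mobility, m^2 V^-1 s^-1 (signed)
#' @param viscosity solvent viscosity, Pa.s (> 0)
#' @param relativePermittivity dimensionless (> 0)
#' @return zeta potential in mV
#' @examples
#' zetaSmoluchowski(-2e-8)   # ~ -25.6 mV in 25 C water
#' @export
zetaSmoluchowski <- function(mobility,
                             viscosity = solventDefaults()$viscosity,
                             relativePermittivity =
                               solventDefaults()$relativePermittivity) {
  if (relativePermittivity <= 0) stop("relative permittivity must be > 0")
  if (viscosity <= 0) stop("viscosity must be > 0")
  1e3 * mobility * viscosity / (.EPSILON0 * relativePermittivity)
}

#' Electrophoretic mobility back from a zeta potential
#'
#' Inverse of [zetaSmoluchowski()]; provided so measured and converted
#' quantities can be round-tripped.
#'
#' @param zeta_mV zeta potential, mV
#' @inheritParams zetaSmoluchowski
#' @return mobility in m^2 V^-1 s^-1
#' @export
mobilityFromZeta <- function(zeta_mV,
                             viscosity = solventDefaults()$viscosity,
                             relativePermittivity =
                               solventDefaults()$relativePermittivity) {
  if (relativePermittivity <= 0) stop("relative permittivity must be > 0")
  if (viscosity <= 0) stop("viscosity must be > 0")
  zeta_mV / 1e3 * .EPSILON0 * relativePermittivity / viscosity
}

#' Particle net charge from mobility and diffusion coefficient
#'
#' Einstein-relation estimate `Q = mu * kB * T / (e * D)` in units of the
#' elementary charge; the friction coefficient implied by the measured
#' diffusion converts mobility to charge. The sign follows the mobility.
#'
#' @param mobility electrophoretic mobility, m^2 V^-1 s^-1 (signed)
#' @param diffusion translational diffusion coefficient, m^2 s^-1 (> 0)
#' @param temperature K (> 0)
#' @return net charge in elementary charges
#' @export
netCharge <- function(mobility, diffusion,
                      temperature = solventDefaults()$temperature) {
  if (any(diffusion <= 0)) stop("diffusion coefficient must be > 0")
  if (any(temperature <= 0)) stop("temperature must be > 0")
  mobility * .KBOLTZ * temperature / (.ECHARGE * diffusion)
}
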