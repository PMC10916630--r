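#' Centrifugal sedimentation rate (CSR)
#'
#' CSR is the mass of sediment recovered after centrifugation, expressed as
#' a percentage of sample mass:
#' \deqn{w_1 = 100 \, (m_2 - m_1) / m_0}
#' where \eqn{m_0} is the sample mass, \eqn{m_1} the empty tube mass and
#' \eqn{m_2} the tube-plus-sediment mass (all in the same mass unit, mg by
#' convention).
#'
#' @param m0 Sample mass, mg; > 0.
#' @param m1 Empty centrifuge tube mass, mg.
#' @param m2 Tube mass after the supernatant is discarded, mg; >= `m1`.
#' @return CSR in percent (>= 0).
#' @examples
#' centrifugal_sedimentation_rate(m0 = 5000, m1 = 10000, m2 = 10041) # 0.82 %
#' @export
centrifugal_sedimentation_rate <- function(m0, m1, m2) {
  stopifnot(is.numeric(m0), is.numeric(m1), is.numeric(m2))
  if (any(m0 <= 0)) stop("sample mass m0 must be > 0", call. = FALSE)
  if (any(m1 < 0)) stop("tube mass m1 must be >= 0", call. = FALSE)
  if (any(m2 < m1)) {
    stop("m2 < m1: sediment mass would be negative", call. = FALSE)
  }
  100 * (m2 - m1) / m0
}

#' Stability coefficient
#'
#' Ratio of the absorbance of the supernatant after centrifugation to the
#' absorbance of the sample before centrifugation, `R = A2/A1`. For a
#' stable dispersion the coefficient is at most 1; values slightly above 1
#' can arise from measurement noise and trigger a warning rather than an
#' error.
#'
#' @param A1 Absorbance before centrifugation; > 0.
#' @param A2 Absorbance of the supernatant after centrifugation; >= 0.
#' @return The dimensionless ratio `A2/A1`.
#' @examples
#' stability_coefficient(A1 = 0.500, A2 = 0.475) # 0.95
#' @export
stability_coefficient <- function(A1, A2) {
  stopifnot(is.numeric(A1), is.numeric(A2))
  if (any(A1 == 0)) stop("A1 must be non-zero", call. = FALSE)
  if (any(A1 < 0) || any(A2 < 0)) {
    stop("absorbances must be non-negative", call. = FALSE)
  }
  r <- A2 / A1
  if (any(r > 1)) {
    warning("stability coefficient > 1; a stable dispersion is expected at <= 1",
            call. = FALSE)
  }
  r
}

#' Stokes sedimentation velocity
#'
#' Terminal settling velocity of a spherical particle in a viscous medium,
#' \deqn{v = g (\rho_1 - \rho_2) d^2 / (18 \eta).}
#' Inputs follow the mixed-unit convention usual in beverage work
#' (densities in g/cm^3, diameter in cm, viscosity in Pa s); everything is
#' converted to SI internally and the result returned in nm/s. The sign of
#' the result follows the sign of the density difference (negative means
#' creaming rather than sedimentation).
#'
#' @param rho_particle Particle density, g/cm^3.
#' @param rho_medium Medium (water) density, g/cm^3.
#' @param diameter Particle diameter, cm; must be < 1 cm.
#' @param viscosity Medium viscosity, Pa s; > 0.
#' @param constants A [physical_constants()] object (supplies `g`).
#' @return Sedimentation velocity in nm/s.
#' @examples
#' # 0.545 um particle, 0.3 g/cm^3 density contrast, water-like viscosity
#' stokes_sedimentation_velocity(1.3, 1.0, 0.545e-4, 1e-3)
#' @export
stokes_sedimentation_velocity <- function(rho_particle, rho_medium,
                                          diameter, viscosity,
                                          constants = physical_constants()) {
  stopifnot(is.numeric(rho_particle), is.numeric(rho_medium),
            is.numeric(diameter), is.numeric(viscosity))
  if (any(viscosity <= 0)) stop("viscosity must be > 0", call. = FALSE)
  if (any(rho_particle <= 0) || any(rho_medium <= 0)) {
    stop("densities must be > 0", call. = FALSE)
  }
  if (any(diameter <= 0) || any(diameter >= 1)) {
    stop("diameter must be in (0, 1) cm", call. = FALSE)
  }
  drho_si <- (rho_particle - rho_medium) * 1000   # g/cm^3 -> kg/m^3
  d_si <- diameter / 100                          # cm -> m
  v_si <- constants$g * drho_si * d_si^2 / (18 * viscosity)  # m/s
  v_si * 1e9                                      # -> nm/s
}
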