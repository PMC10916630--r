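#' Published soymilk storage-kinetics constants
#'
#' The reference constants for soymilk produced by the repeated
#' boiling-to-filtering method (RBFM), as reported in the storage study the
#' package models: first-order rate constants and activation energies per
#' stability index and temperature, the Gibbs-energy-versus-temperature
#' regression coefficients, the sensory-score linkage regressions, and the
#' initial index values. These ship as a fixture so the synthetic-data
#' generator and the worked examples can reproduce the published analysis
#' without access to the raw storage measurements (which were never
#' deposited).
#'
#' Two idiosyncrasies of the published table are preserved verbatim: the
#' particle-size activation energy is printed as 38.58 kJ/mol in two rows
#' and 38.56 in the third, and the viscosity rate constant at 298.15 K
#' (0.0630 d^-1) is non-monotone against the higher temperatures. Each row
#' is reproduced with its own printed values.
#'
#' @return A list with elements:
#' \describe{
#'   \item{kinetics}{data frame: `index_name`, `temperature` (K), `k`
#'     (d^-1), `Ea` (J/mol), `direction`.}
#'   \item{gibbs}{data frame of published dG*(T) regressions: `index_name`,
#'     `slope` (kJ/(mol K)), `intercept` (kJ/mol), `r_squared`.}
#'   \item{sensory}{data frame of sensory-score linkages SS = slope * C +
#'     intercept: `index_name`, `slope`, `intercept`, `r_squared`.}
#'   \item{C0}{named numeric: initial index values (CSR %, particle size
#'     um, viscosity mPa s).}
#'   \item{threshold}{sensory acceptance limit, 80 points.}
#' }
#' @examples
#' soymilk_fixture()$kinetics
#' @export
soymilk_fixture <- function() {
  kinetics <- data.frame(
    index_name = rep(c("CSR", "particle_size", "viscosity"), each = 3L),
    temperature = rep(c(298.15, 308.15, 318.15), times = 3L),
    k = c(0.0367, 0.0678, 0.1013,
          0.0158, 0.0270, 0.0420,
          0.0630, 0.0112, 0.0168),
    Ea = c(40800, 40800, 40800,
           38580, 38580, 38560,
           10560, 10560, 10560),
    direction = c(1, 1, 1, 1, 1, 1, -1, -1, -1),
    stringsAsFactors = FALSE
  )
  gibbs <- data.frame(
    index_name = c("CSR", "particle_size", "viscosity"),
    slope = c(0.1467, 0.1587, 0.4513),
    intercept = c(37.398, 35.964, -53.788),
    r_squared = c(0.9918, 0.9991, 0.8951),
    stringsAsFactors = FALSE
  )
  sensory <- data.frame(
    index_name = c("CSR", "particle_size", "viscosity"),
    slope = c(-9.6927, -33.187, 10.322),
    intercept = c(96.131, 105.79, -28.007),
    r_squared = c(0.9868, 0.9796, 0.9558),
    stringsAsFactors = FALSE
  )
  list(
    kinetics = kinetics,
    gibbs = gibbs,
    sensory = sensory,
    C0 = c(CSR = 0.82, particle_size = 0.545, viscosity = 5.82),
    threshold = 80
  )
}
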