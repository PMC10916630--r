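#' Arrhenius activation-energy estimation
#'
#' Fits the Arrhenius law \eqn{k = A_0 \exp(-E_a / RT)} to rate constants
#' measured at several temperatures, by ordinary least squares of
#' \eqn{\ln k} on \eqn{1/T}: the activation energy is \eqn{E_a = -R \times}
#' slope and the pre-exponential factor \eqn{A_0 = \exp(} intercept \eqn{)}.
#'
#' Duplicate temperatures with conflicting rate constants collapse to their
#' geometric mean (the natural average on the log scale) with a warning.
#'
#' @param temperatures Absolute temperatures, K; at least two distinct.
#' @param k Rate constants at those temperatures, d^-1; all > 0.
#' @param constants A [physical_constants()] object.
#' @return An object of class `arrhenius_fit`: list with `Ea` (J/mol),
#'   `A0` (d^-1), `r_squared`.
#' @examples
#' fit_arrhenius(c(298.15, 308.15, 318.15), c(0.0367, 0.0678, 0.1013))
#' @export
fit_arrhenius <- function(temperatures, k,
                          constants = physical_constants()) {
  stopifnot(length(temperatures) == length(k))
  if (any(k <= 0)) stop("all rate constants must be > 0", call. = FALSE)
  if (any(temperatures <= 0)) stop("temperatures must be > 0 K", call. = FALSE)
  if (anyDuplicated(temperatures)) {
    warning("duplicate temperatures: collapsing rate constants to geometric means",
            call. = FALSE)
    lk <- tapply(log(k), temperatures, mean)
    temperatures <- as.numeric(names(lk))
    k <- exp(as.numeric(lk))
  }
  if (length(unique(temperatures)) < 2L) {
    stop("at least two distinct temperatures are required", call. = FALSE)
  }
  x <- 1 / temperatures
  y <- log(k)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  structure(
    list(Ea = -slope * constants$R_gas, A0 = exp(intercept),
         r_squared = r_squared_linear(y, stats::fitted(fit))),
    class = "arrhenius_fit"
  )
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius fit: Ea = %.4g kJ/mol, A0 = %.4g d^-1, r^2 = %.4f\n",
              x$Ea / 1000, x$A0, x$r_squared))
  invisible(x)
}

#' Eyring transition-state parameters at one temperature
#'
#' From a first-order rate constant and activation energy, computes the
#' activation enthalpy, entropy and Gibbs free energy:
#' \deqn{\Delta H^* = E_a - RT}
#' \deqn{\Delta S^* = R(\ln k' - \ln(k_b/h) - \ln T - 1) + E_a/T}
#' \deqn{\Delta G^* = \Delta H^* - T \Delta S^*}
#'
#' The `convention` argument controls what \eqn{k'} is. Under
#' `"per_day_numeric"` (the default) the numeric value of the rate constant
#' in d^-1 is inserted directly into the expression alongside the SI value
#' of \eqn{k_b/h}. This mixes a per-day rate with per-second universal
#' constants and is therefore dimensionally inconsistent, but it is the
#' convention in widespread use in food storage-kinetics tables, and the
#' published soymilk parameters are only reproducible under it. Under
#' `"per_second_SI"` the rate is first converted to s^-1 (divided by
#' 86400), which is the physically consistent choice; \eqn{\Delta S^*}
#' then shifts by \eqn{-R \ln 86400 \approx -94.5} J/(mol K) and
#' \eqn{\Delta G^*} correspondingly.
#'
#' @param temperature Absolute temperature, K.
#' @param k First-order rate constant, d^-1; > 0.
#' @param Ea Activation energy, J/mol.
#' @param constants A [physical_constants()] object.
#' @param convention `"per_day_numeric"` or `"per_second_SI"`.
#' @return An object of class `eyring_row`: list with `temperature`, `k`,
#'   `Ea`, `dH`, `dS`, `dG` (J/mol and J/(mol K)), and `convention`.
#' @examples
#' eyring_parameters(298.15, k = 0.0367, Ea = 40800)
#' @export
eyring_parameters <- function(temperature, k, Ea,
                              constants = physical_constants(),
                              convention = c("per_day_numeric",
                                             "per_second_SI")) {
  convention <- match.arg(convention)
  if (k <= 0) stop("rate constant must be > 0", call. = FALSE)
  if (temperature <= 0) stop("temperature must be > 0 K", call. = FALSE)
  R <- constants$R_gas
  k_num <- if (convention == "per_second_SI") k / SECONDS_PER_DAY else k
  dH <- Ea - R * temperature
  dS <- R * (log(k_num) - log(constants$k_b / constants$h_planck) -
               log(temperature) - 1) + Ea / temperature
  dG <- dH - temperature * dS
  structure(
    list(temperature = temperature, k = k, Ea = Ea,
         dH = dH, dS = dS, dG = dG, convention = convention),
    class = "eyring_row"
  )
}

#' @export
print.eyring_row <- function(x, ...) {
  cat(sprintf(
    "Eyring row (%s): T = %.2f K, k = %.4g d^-1, Ea = %.4g kJ/mol\n",
    x$convention, x$temperature, x$k, x$Ea / 1000))
  cat(sprintf(
    "  dH* = %.2f kJ/mol, dS* = %.2f J/(mol K), dG* = %.2f kJ/mol\n",
    x$dH / 1000, x$dS, x$dG / 1000))
  invisible(x)
}

#' Rate constant implied by Eyring parameters (round trip)
#'
#' Evaluates \eqn{(k_b T / h) \exp(\Delta S^*/R) \exp(-\Delta H^*/(RT))}
#' and converts back to d^-1 according to the row's rate convention. On any
#' row produced by [eyring_parameters()] this reproduces the input rate
#' constant to floating-point accuracy.
#'
#' @param row An `eyring_row`.
#' @param constants A [physical_constants()] object.
#' @return Rate constant, d^-1.
#' @export
eyring_rate <- function(row, constants = physical_constants()) {
  stopifnot(inherits(row, "eyring_row"))
  R <- constants$R_gas
  Tk <- row$temperature
  k_num <- (constants$k_b * Tk / constants$h_planck) *
    exp(row$dS / R) * exp(-row$dH / (R * Tk))
  if (row$convention == "per_second_SI") k_num * SECONDS_PER_DAY else k_num
}

#' Gibbs-energy-versus-temperature regression
#'
#' The Gibbs free energy of activation of a storage index increases roughly
#' linearly with storage temperature; regressing \eqn{\Delta G^*} (kJ/mol)
#' on \eqn{T} (K) gives a two-coefficient summary that the shelf-life model
#' uses to interpolate the rate constant at arbitrary temperatures.
#'
#' @param temperatures Absolute temperatures, K; at least two distinct.
#' @param dG_kJ Gibbs free energies of activation, kJ/mol.
#' @return An object of class `gibbs_temp_fit`: list with `slope`
#'   (kJ/(mol K)), `intercept` (kJ/mol), `r_squared`.
#' @examples
#' fit_gibbs_temperature(c(298.15, 308.15, 318.15), c(81.21, 82.45, 84.15))
#' @export
fit_gibbs_temperature <- function(temperatures, dG_kJ) {
  stopifnot(length(temperatures) == length(dG_kJ))
  if (length(unique(temperatures)) < 2L) {
    stop("at least two distinct temperatures are required", call. = FALSE)
  }
  fit <- stats::lm(dG_kJ ~ temperatures)
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = r_squared_linear(dG_kJ, stats::fitted(fit))),
    class = "gibbs_temp_fit"
  )
}

#' @export
print.gibbs_temp_fit <- function(x, ...) {
  cat(sprintf("dG*(T) = %.4f T %+.3f kJ/mol, r^2 = %.4f\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}
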