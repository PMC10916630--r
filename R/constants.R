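#' Physical constants used throughout the package
#'
#' Returns the set of physical constants the kinetic and thermodynamic
#' formulas depend on. Values follow the conventional rounded figures used
#' in food-kinetics work rather than full CODATA precision, so that
#' recomputed tables agree with hand calculations at the printed precision.
#'
#' @param g Gravitational acceleration, m/s^2.
#' @param R_gas Gas constant, J/(mol K).
#' @param k_b Boltzmann constant, J/K.
#' @param h_planck Planck constant, J s.
#'
#' @return An object of class `physical_constants`: a named list with
#'   elements `g`, `R_gas`, `k_b`, `h_planck`.
#'
#' @examples
#' cst <- physical_constants()
#' cst$R_gas
#' @export
physical_constants <- function(g = 9.80, R_gas = 8.314,
                               k_b = 1.38e-23, h_planck = 6.626e-34) {
  vals <- c(g = g, R_gas = R_gas, k_b = k_b, h_planck = h_planck)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all physical constants must be finite and strictly positive",
         call. = FALSE)
  }
  structure(list(g = g, R_gas = R_gas, k_b = k_b, h_planck = h_planck),
            class = "physical_constants")
}

#' @export
print.physical_constants <- function(x, ...) {
  cat("Physical constants:\n")
  cat(sprintf("  g        = %.4g m/s^2\n", x$g))
  cat(sprintf("  R_gas    = %.4g J/(mol K)\n", x$R_gas))
  cat(sprintf("  k_b      = %.4g J/K\n", x$k_b))
  cat(sprintf("  h_planck = %.4g J s\n", x$h_planck))
  invisible(x)
}

# seconds per day; used only when converting rate constants to SI
SECONDS_PER_DAY <- 86400
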