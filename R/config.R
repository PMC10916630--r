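#' Load an analysis configuration
#'
#' Reads a YAML or JSON mapping of run settings. Unknown keys are rejected
#' so that typos do not silently fall back to defaults.
#'
#' Recognised keys (all optional):
#' \describe{
#'   \item{g, R_gas, k_b, h_planck}{overrides for [physical_constants()].
#'     Overriding `R_gas` away from 8.314 is accepted but logged loudly,
#'     as an escape hatch for forensic reproduction of published tables
#'     that used a different numeric value.}
#'   \item{eyring_rate_convention}{`"per_day_numeric"` (default) or
#'     `"per_second_SI"`; see [eyring_parameters()].}
#'   \item{threshold}{sensory acceptance limit, points; default 80.}
#'   \item{seed}{integer seed for the synthetic-data generator.}
#' }
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file, or `NULL` for all
#'   defaults.
#' @return A named list with elements `constants`, `convention`,
#'   `threshold`, `seed`.
#' @export
load_config <- function(path = NULL) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop(sprintf("config file not found: %s", path), call. = FALSE)
    }
    raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (is.null(raw)) raw <- list()
  }
  known <- c("g", "R_gas", "k_b", "h_planck",
             "eyring_rate_convention", "threshold", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  cst_args <- raw[intersect(names(raw), c("g", "R_gas", "k_b", "h_planck"))]
  if (!is.null(cst_args$R_gas) && abs(cst_args$R_gas - 8.314) > 1e-9) {
    warning(sprintf(
      "R_gas overridden to %g J/(mol K); downstream thermodynamics will use this value",
      cst_args$R_gas), call. = FALSE)
  }
  constants <- do.call(physical_constants, cst_args)
  convention <- raw$eyring_rate_convention %||% "per_day_numeric"
  convention <- match.arg(convention, c("per_day_numeric", "per_second_SI"))
  threshold <- raw$threshold %||% 80
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("threshold must be a positive number of sensory points", call. = FALSE)
  }
  seed <- raw$seed %||% 1L
  sk_log("load_config: convention=%s threshold=%g seed=%d",
         convention, threshold, as.integer(seed))
  list(constants = constants, convention = convention,
       threshold = threshold, seed = as.integer(seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
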