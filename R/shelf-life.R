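#' Sensory-score linkage regression
#'
#' Regresses the sensory score on a stability index over all storage times
#' and temperatures pooled, giving the linear bridge SS = slope * C +
#' intercept that the shelf-life model composes with the kinetic model of
#' the index. The two inputs must cover identical (temperature, time)
#' support; unmatched points are an error, listed explicitly, because a
#' silent inner join could pair scores with the wrong storage condition.
#'
#' @param sensory A [storage_series()] of sensory scores, or a list of them
#'   (one per temperature).
#' @param index A [storage_series()] of the stability index, or a list of
#'   them, on the same support.
#' @return An object of class `sensory_fit`: list with `index_name`,
#'   `slope` (points per index unit), `intercept` (points), `r_squared`.
#' @examples
#' t <- seq(0, 40, by = 4)
#' csr <- storage_series("CSR", 298.15, t, 0.82 * exp(0.0367 * t))
#' ss <- storage_series("sensory_score", 298.15, t,
#'                      -9.6927 * csr$values + 96.131)
#' fit_sensory_regression(ss, csr)
#' @export
fit_sensory_regression <- function(sensory, index) {
  stack <- function(x) {
    if (inherits(x, "storage_series")) x <- list(x)
    do.call(rbind, lapply(x, as.data.frame))
  }
  sdf <- stack(sensory)
  idf <- stack(index)
  skey <- paste(sdf$temperature_K, sdf$time_d)
  ikey <- paste(idf$temperature_K, idf$time_d)
  unmatched <- c(setdiff(skey, ikey), setdiff(ikey, skey))
  if (length(unmatched) > 0L) {
    stop(sprintf("sensory/index support mismatch at (T K, t d): %s",
                 paste(unique(unmatched), collapse = "; ")), call. = FALSE)
  }
  m <- merge(sdf, idf, by = c("temperature_K", "time_d"),
             suffixes = c("_ss", "_idx"))
  if (nrow(m) < 3L) {
    stop("at least 3 paired points are required", call. = FALSE)
  }
  fit <- stats::lm(value_ss ~ value_idx, data = m)
  slope <- unname(stats::coef(fit)[2L])
  # a constant score has no linear association with the index
  if (stats::var(m$value_ss) == 0) slope <- 0
  structure(
    list(index_name = idf$index[1L],
         slope = slope,
         intercept = if (slope == 0) mean(m$value_ss)
                     else unname(stats::coef(fit)[1L]),
         r_squared = if (stats::var(m$value_ss) == 0) 0
                     else r_squared_linear(m$value_ss, stats::fitted(fit))),
    class = "sensory_fit"
  )
}

#' @export
print.sensory_fit <- function(x, ...) {
  cat(sprintf("Sensory linkage: SS = %.4f * %s %+.3f, r^2 = %.4f\n",
              x$slope, x$index_name, x$intercept, x$r_squared))
  invisible(x)
}

#' Select the key stability index
#'
#' Among several sensory-linkage regressions, returns the one with the
#' highest coefficient of determination — the index that tracks the
#' sensory score most faithfully and therefore anchors the shelf-life
#' model. Exact ties break to the lexicographically first index name.
#'
#' @param fits A non-empty list of `sensory_fit` objects.
#' @return The selected `sensory_fit`.
#' @export
select_key_index <- function(fits) {
  if (length(fits) == 0L) stop("no sensory fits supplied", call. = FALSE)
  r2 <- vapply(fits, function(f) f$r_squared, numeric(1))
  nm <- vapply(fits, function(f) f$index_name, character(1))
  best <- order(-r2, nm)[1L]
  fits[[best]]
}

#' Construct a combined kinetic-sensory shelf-life model
#'
#' Couples three fitted pieces into one predictive equation for the sensory
#' score as a function of storage time and temperature:
#' \deqn{SS(t, T) = a \, C_0 \, e^{k(T) t} + b}
#' where \eqn{(a, b)} are the sensory-linkage coefficients for the key
#' index, \eqn{C_0} is the initial value of that index, and the rate
#' constant is interpolated from the Gibbs-energy regression through the
#' Eyring relation
#' \deqn{k(T) = (k_b T / h) \exp(-\Delta G^*(T) / RT),}
#' with \eqn{\Delta G^*(T)} in kJ/mol converted to J/mol internally.
#'
#' @param sensory A `sensory_fit` for the key index.
#' @param gibbs A `gibbs_temp_fit` for the same index.
#' @param C0 Initial value of the key index, index units; > 0.
#' @param constants A [physical_constants()] object.
#' @param convention Rate convention, as in [eyring_parameters()]; under
#'   the default `"per_day_numeric"` the interpolated rate is read in
#'   d^-1.
#' @param threshold Sensory acceptance limit, points; default 80. Must lie
#'   strictly below the initial score `SS(0) = slope * C0 + intercept`.
#' @param direction +1 if the key index grows during storage (default),
#'   -1 if it decays.
#' @return An object of class `shelf_life_model`.
#' @examples
#' fx <- soymilk_fixture()
#' m <- shelf_life_model(
#'   sensory = structure(as.list(fx$sensory[1, -1]), class = "sensory_fit",
#'                       index_name = "CSR"),
#'   gibbs = structure(as.list(fx$gibbs[1, 2:4]), class = "gibbs_temp_fit"),
#'   C0 = fx$C0[["CSR"]])
#' solve_shelf_life(m, 298.15)
#' @export
shelf_life_model <- function(sensory, gibbs, C0,
                             constants = physical_constants(),
                             convention = c("per_day_numeric",
                                            "per_second_SI"),
                             threshold = 80, direction = 1) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(C0), length(C0) == 1L, C0 > 0)
  if (!all(c("slope", "intercept") %in% names(sensory))) {
    stop("sensory must carry slope and intercept", call. = FALSE)
  }
  if (!all(c("slope", "intercept") %in% names(gibbs))) {
    stop("gibbs must carry slope and intercept", call. = FALSE)
  }
  if (direction > 0 && sensory$slope >= 0) {
    stop("a growing key index needs a negative sensory slope for the score to decline",
         call. = FALSE)
  }
  if (direction < 0 && sensory$slope <= 0) {
    stop("a decaying key index needs a positive sensory slope for the score to decline",
         call. = FALSE)
  }
  ss0 <- sensory$slope * C0 + sensory$intercept
  # equality is allowed and yields a zero shelf life
  if (threshold > ss0) {
    stop(sprintf("threshold (%.3f) must lie below the initial score SS(0) = %.3f",
                 threshold, ss0), call. = FALSE)
  }
  structure(
    list(sensory = sensory, gibbs = gibbs, C0 = C0,
         constants = constants, convention = convention,
         threshold = threshold, direction = direction),
    class = "shelf_life_model"
  )
}

#' @export
print.shelf_life_model <- function(x, ...) {
  cat(sprintf(
    "Shelf-life model (key index %s): SS(t,T) = %.4f * %.4g * exp(k(T) t) %+.3f\n",
    x$sensory$index_name %||% "?", x$sensory$slope, x$C0,
    x$sensory$intercept))
  cat(sprintf("  dG*(T) = %.4f T %+.3f kJ/mol; threshold %.1f points; %s\n",
              x$gibbs$slope, x$gibbs$intercept, x$threshold, x$convention))
  invisible(x)
}

#' Rate constant interpolated from the Gibbs-energy regression
#'
#' @param model A [shelf_life_model()].
#' @param temperature Absolute temperature, K (vectorized).
#' @return Rate constant(s), d^-1 under `per_day_numeric`.
#' @export
rate_from_gibbs <- function(model, temperature) {
  stopifnot(inherits(model, "shelf_life_model"))
  cst <- model$constants
  dG_J <- 1000 * (model$gibbs$slope * temperature + model$gibbs$intercept)
  k_num <- (cst$k_b * temperature / cst$h_planck) *
    exp(-dG_J / (cst$R_gas * temperature))
  if (model$convention == "per_second_SI") k_num * SECONDS_PER_DAY else k_num
}

#' Predict the sensory score at a storage time and temperature
#'
#' @param model A [shelf_life_model()].
#' @param t Storage time, days; >= 0 (vectorized).
#' @param temperature Absolute temperature, K.
#' @return Predicted sensory score, points.
#' @export
predict_sensory <- function(model, t, temperature) {
  stopifnot(inherits(model, "shelf_life_model"))
  if (any(t < 0)) stop("storage time must be >= 0", call. = FALSE)
  k <- rate_from_gibbs(model, temperature)
  model$sensory$slope * model$C0 * exp(model$direction * k * t) +
    model$sensory$intercept
}

#' Solve the model for shelf life at a temperature
#'
#' Inverts the combined equation in closed form: the time at which the
#' predicted sensory score reaches the acceptance threshold,
#' \deqn{t = \ln\left(\frac{b - SS_{lim}}{-a C_0}\right) / k(T)}
#' for a growing key index with sensory slope \eqn{a < 0} and intercept
#' \eqn{b}.
#'
#' @param model A [shelf_life_model()].
#' @param temperature Absolute temperature, K.
#' @return Shelf life, days.
#' @export
solve_shelf_life <- function(model, temperature) {
  stopifnot(inherits(model, "shelf_life_model"))
  s <- model$sensory$slope
  ss0 <- s * model$C0 + model$sensory$intercept
  if (model$threshold > ss0) {
    stop(sprintf("threshold (%.3f) exceeds initial score SS(0) = %.3f",
                 model$threshold, ss0), call. = FALSE)
  }
  if (model$threshold == ss0) return(0)
  # SS(t) = s*C0*exp(d*k*t) + b  =>  exp(d*k*t) = (threshold - b)/(s*C0)
  ratio <- (model$threshold - model$sensory$intercept) / (s * model$C0)
  if (!is.finite(ratio) || ratio <= 0) {
    stop(sprintf("threshold is outside the model's reachable score range (ratio %.4g)",
                 ratio), call. = FALSE)
  }
  k <- rate_from_gibbs(model, temperature)
  t <- log(ratio) / (model$direction * k)
  if (t < 0) {
    stop("threshold is not reachable: the predicted score never declines to it",
         call. = FALSE)
  }
  t
}

#' Prediction-error statistics for shelf-life validation
#'
#' Standard error of prediction and residual variation coefficient:
#' \deqn{S_e = \sqrt{\sum_i (y_i - \hat y_i)^2 / (n - k - 1)}, \quad
#'       V_e = 100 \, S_e / \bar y}
#' where \eqn{y_i} are observed shelf lives, \eqn{\hat y_i} the model's
#' predictions and \eqn{k} the number of prediction factors. The customary
#' adequacy rule for beverages is `Ve < 15` percent.
#'
#' @param observed Observed shelf lives, days.
#' @param predicted Predicted shelf lives, days; same length.
#' @param k_pred Number of prediction factors; `n > k_pred + 1` required.
#' @return An object of class `validation_stats`: list with `Se` (days),
#'   `Ve` (percent), `n`, `k_pred`, `passes` (`Ve < 15`).
#' @examples
#' validate_predictions(c(90, 120, 150), c(80, 110, 160), k_pred = 1)
#' @export
validate_predictions <- function(observed, predicted, k_pred = 1) {
  n <- length(observed)
  if (length(predicted) != n) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  if (n <= k_pred + 1) {
    stop(sprintf("no residual degrees of freedom: n = %d, k_pred = %d",
                 n, k_pred), call. = FALSE)
  }
  Se <- sqrt(sum((observed - predicted)^2) / (n - k_pred - 1))
  Ve <- 100 * Se / mean(observed)
  structure(
    list(Se = Se, Ve = Ve, n = n, k_pred = k_pred, passes = Ve < 15),
    class = "validation_stats"
  )
}

#' @export
print.validation_stats <- function(x, ...) {
  cat(sprintf("Validation: Se = %.3f d, Ve = %.2f%% (n = %d, k = %d) -> %s\n",
              x$Se, x$Ve, x$n, x$k_pred,
              if (x$passes) "adequate (Ve < 15%)" else "inadequate"))
  invisible(x)
}
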