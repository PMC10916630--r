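#' Configuration for the synthetic storage-data generator
#'
#' Describes the simulated storage experiment: per-index kinetic
#' parameters, the temperature arms, the sampling schedule, noise levels,
#' and the sensory linkage. Defaults reproduce the published RBFM soymilk
#' study conditions (see [soymilk_fixture()]): three temperature arms at
#' 25/35/45 degrees C, six parallel bottles per sampling point, and the
#' published first-order rate constants and linkage coefficients.
#'
#' Noise is multiplicative lognormal on index values (keeps them positive
#' and matches the log-linear fitting the analysis applies) and additive
#' Gaussian on sensory points.
#'
#' @param kinetics Data frame with columns `index_name`, `temperature`
#'   (K), `k` (d^-1), `C0`, `direction`, `order`. Default: the published
#'   first-order constants with their initial values.
#' @param times Sampling schedule, days; ten equally spaced samples by
#'   default. The default 2-day interval (0-18 d) keeps every default
#'   kinetic arm inside the index ranges observed in the reference study,
#'   so linked sensory scores stay on the 0-100 scale without clipping.
#' @param noise_sigma Lognormal sigma for index values (on the log scale).
#' @param sensory_noise_sigma Additive sigma for sensory points.
#' @param replicates Parallel samples per point; default 6.
#' @param seed Integer RNG seed.
#' @param sensory_link Data frame `index_name`, `slope`, `intercept` used
#'   by [generate_sensory_series()]; default the published linkages.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(kinetics = NULL,
                             times = seq(0, 18, by = 2),
                             noise_sigma = 0.05,
                             sensory_noise_sigma = 0.5,
                             replicates = 6L,
                             seed = 1L,
                             sensory_link = NULL) {
  if (is.null(kinetics)) {
    fx <- soymilk_fixture()
    kinetics <- fx$kinetics
    kinetics$C0 <- unname(fx$C0[kinetics$index_name])
    kinetics$order <- 1L
    kinetics <- kinetics[c("index_name", "temperature", "k", "C0",
                           "direction", "order")]
  }
  if (is.null(sensory_link)) {
    sensory_link <- soymilk_fixture()$sensory[c("index_name", "slope",
                                                "intercept")]
  }
  need <- c("index_name", "temperature", "k", "C0", "direction", "order")
  if (!all(need %in% names(kinetics))) {
    stop(sprintf("kinetics must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  stopifnot(all(kinetics$k >= 0), all(kinetics$C0 > 0),
            noise_sigma >= 0, sensory_noise_sigma >= 0, replicates >= 1)
  # an order-0 decay must not cross zero inside the schedule
  z <- kinetics$order == 0L & kinetics$direction < 0 &
    kinetics$C0 - kinetics$k * max(times) <= 0
  if (any(z)) {
    stop(sprintf("order-0 trajectory crosses zero within the schedule: %s",
                 paste(kinetics$index_name[z], collapse = ", ")),
         call. = FALSE)
  }
  structure(
    list(kinetics = kinetics, times = as.numeric(times),
         noise_sigma = noise_sigma,
         sensory_noise_sigma = sensory_noise_sigma,
         replicates = as.integer(replicates), seed = as.integer(seed),
         sensory_link = sensory_link),
    class = "synthetic_config"
  )
}

# noiseless kinetic trajectory
trajectory <- function(order, C0, k, direction, t) {
  if (order == 1L) C0 * exp(direction * k * t)
  else C0 + direction * k * t
}

# evaluate expr under a private RNG stream, restoring global state after
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate synthetic storage series
#'
#' Simulates the storage experiment described by a [synthetic_config()].
#' For a first-order index, replicate values are
#' \eqn{C(t) = C_0 e^{d k t} \varepsilon} with
#' \eqn{\ln \varepsilon \sim N(0, \sigma^2)}; for order 0 the trajectory is
#' linear with additive Gaussian noise of the same sigma (in index units).
#' Each (index, temperature) arm and replicate draws from its own RNG
#' substream derived from the configuration seed, so arms are statistically
#' independent and any subset regenerates identically.
#'
#' @param config A [synthetic_config()].
#' @param emit `"means"` (default) for one series of replicate means per
#'   arm, `"replicates"` for one series per replicate.
#' @return A named list of [storage_series()].
#' @examples
#' cfg <- synthetic_config(noise_sigma = 0, replicates = 1)
#' generate_storage_series(cfg)[["CSR@298.15K"]]
#' @export
generate_storage_series <- function(config, emit = c("means", "replicates")) {
  stopifnot(inherits(config, "synthetic_config"))
  emit <- match.arg(emit)
  kin <- config$kinetics
  t <- config$times
  out <- list()
  for (i in seq_len(nrow(kin))) {
    row <- kin[i, ]
    clean <- trajectory(row$order, row$C0, row$k, row$direction, t)
    # substream per arm: offset by row index, large stride
    reps <- with_seed(config$seed + 7919L * i, {
      vapply(seq_len(config$replicates), function(r) {
        if (row$order == 1L) {
          clean * exp(stats::rnorm(length(t), 0, config$noise_sigma))
        } else {
          clean + stats::rnorm(length(t), 0, config$noise_sigma)
        }
      }, numeric(length(t)))
    })
    reps <- matrix(reps, nrow = length(t))
    key <- sprintf("%s@%gK", row$index_name, row$temperature)
    if (emit == "means") {
      out[[key]] <- storage_series(row$index_name, row$temperature, t,
                                   rowMeans(reps))
    } else {
      for (r in seq_len(config$replicates)) {
        out[[sprintf("%s#rep%d", key, r)]] <-
          storage_series(row$index_name, row$temperature, t, reps[, r])
      }
    }
  }
  sk_log("generate_storage_series: %d arm(s), %d time point(s), %d replicate(s), emit=%s",
         nrow(kin), length(t), config$replicates, emit)
  out
}

#' Generate a sensory-score series linked to an index series
#'
#' Applies the linear linkage SS = slope * C + intercept to an index
#' series, adds Gaussian noise, and clips to the 0-100 point scale.
#'
#' @param index_series A [storage_series()] of the stability index.
#' @param slope,intercept Linkage coefficients, points per index unit and
#'   points.
#' @param noise_sigma Additive noise sigma, points.
#' @param seed Integer RNG seed.
#' @return A [storage_series()] named `"sensory_score"`.
#' @export
generate_sensory_series <- function(index_series, slope, intercept,
                                    noise_sigma = 0, seed = 1L) {
  stopifnot(inherits(index_series, "storage_series"),
            is.finite(slope), is.finite(intercept), noise_sigma >= 0)
  ss <- slope * index_series$values + intercept
  if (noise_sigma > 0) {
    ss <- ss + with_seed(seed, stats::rnorm(length(ss), 0, noise_sigma))
  }
  ss <- pmin(pmax(ss, 0), 100)
  storage_series("sensory_score", index_series$temperature,
                 index_series$times, ss)
}

#' Parameter-recovery experiment
#'
#' The harness for checking that the full analysis chain recovers its own
#' generating constants: for each replication, generates a fresh synthetic
#' dataset, fits the first-order model per arm, fits the Arrhenius law per
#' index, and computes Eyring parameters; then summarizes the relative
#' errors of the recovered rate constants, activation energies and Gibbs
#' energies against the generating values.
#'
#' @param config A [synthetic_config()]; each replication uses seed
#'   `config$seed + replication`.
#' @param replications Number of independent replications; >= 1.
#' @param constants A [physical_constants()] object.
#' @return A list with data frames `k` (per arm), `Ea` and `dG` (per
#'   index), each carrying `median_rel_err` and `p95_rel_err`, plus the
#'   raw per-replication relative errors in `errors`.
#' @export
recovery_experiment <- function(config, replications = 100L,
                                constants = physical_constants()) {
  stopifnot(inherits(config, "synthetic_config"), replications >= 1)
  old_opt <- options(shelfkin.verbose = FALSE)  # one line per rep is noise
  on.exit(options(old_opt))
  kin <- config$kinetics
  arms <- sprintf("%s@%gK", kin$index_name, kin$temperature)
  indices <- unique(kin$index_name)

  k_err <- matrix(NA_real_, replications, length(arms),
                  dimnames = list(NULL, arms))
  ea_err <- dg_err <- matrix(NA_real_, replications, length(indices),
                             dimnames = list(NULL, indices))
  for (rep in seq_len(replications)) {
    cfg <- config
    cfg$seed <- config$seed + rep
    series <- generate_storage_series(cfg, emit = "means")
    fits <- lapply(series, fit_rate_constant, order = 1)
    k_hat <- vapply(fits, function(f) f$k, numeric(1))[arms]
    k_err[rep, ] <- abs(k_hat - kin$k) / kin$k
    for (ix in indices) {
      sel <- kin$index_name == ix
      arr <- fit_arrhenius(kin$temperature[sel], k_hat[arms[sel]],
                           constants = constants)
      # truth from the same estimator applied to the generating constants
      arr_true <- fit_arrhenius(kin$temperature[sel], kin$k[sel],
                                constants = constants)
      ea_err[rep, ix] <- abs(arr$Ea - arr_true$Ea) / abs(arr_true$Ea)
      dg_hat <- eyring_parameters(kin$temperature[sel][1L],
                                  k_hat[arms[sel]][1L], arr$Ea,
                                  constants = constants)$dG
      dg_true <- eyring_parameters(kin$temperature[sel][1L],
                                   kin$k[sel][1L], arr_true$Ea,
                                   constants = constants)$dG
      dg_err[rep, ix] <- abs(dg_hat - dg_true) / abs(dg_true)
    }
  }
  summarize <- function(m) {
    data.frame(name = colnames(m),
               median_rel_err = apply(m, 2, stats::median),
               p95_rel_err = apply(m, 2, stats::quantile, probs = 0.95),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  list(k = summarize(k_err), Ea = summarize(ea_err), dG = summarize(dg_err),
       errors = list(k = k_err, Ea = ea_err, dG = dg_err))
}
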