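#' Run the full storage-stability analysis pipeline
#'
#' Composes the stages of the analysis — ingest or simulate storage series,
#' fit kinetics per (index, temperature) arm, estimate Arrhenius and Eyring
#' thermodynamics per index, regress Gibbs energy on temperature, link the
#' sensory score to each index, build the combined shelf-life model on the
#' key index, and predict shelf life at the requested temperatures — and
#' writes one CSV per stage plus a JSON run manifest. Each stage is a pure
#' function of its inputs, so a rerun with the same manifest settings
#' reproduces every output byte for byte.
#'
#' If the input contains no `sensory_score` series the pipeline completes
#' through the thermodynamic stage and records the shelf-life stage as
#' skipped.
#'
#' @param input Path to a series CSV in the [read_series_csv()] dialect, or
#'   `NULL` to simulate from `synthetic`.
#' @param out_dir Output directory; created if absent.
#' @param config A configuration record from [load_config()].
#' @param synthetic A [synthetic_config()] used when `input` is `NULL`.
#' @param temperatures Temperatures (K) at which to predict shelf life;
#'   default the temperatures present in the data.
#' @return The run manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(input = NULL, out_dir = tempfile("shelfkin_run_"),
                         config = load_config(), synthetic = NULL,
                         temperatures = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  # --- stage 1: data -------------------------------------------------
  if (is.null(input)) {
    if (is.null(synthetic)) synthetic <- synthetic_config(seed = config$seed)
    series <- generate_storage_series(synthetic, emit = "means")
    # attach sensory arms linked to each index arm that has a linkage
    link <- synthetic$sensory_link
    sensory <- list()
    for (nm in names(series)) {
      s <- series[[nm]]
      row <- link[link$index_name == s$index_name, ]
      if (nrow(row) == 1L && s$index_name == "CSR") {
        sensory[[sprintf("sensory_score@%gK", s$temperature)]] <-
          generate_sensory_series(s, row$slope, row$intercept,
                                  noise_sigma = synthetic$sensory_noise_sigma,
                                  seed = synthetic$seed + 104729L +
                                    round(s$temperature))
      }
    }
    series <- c(series, sensory)
    input_df <- do.call(rbind, lapply(series, as.data.frame))
    paths$input <- file.path(out_dir, "series.csv")
    utils::write.csv(input_df, paths$input, row.names = FALSE, quote = FALSE)
  } else {
    if (!file.exists(input)) stop(sprintf("input not found: %s", input),
                                  call. = FALSE)
    paths$input <- input
    series <- read_series_csv(input)
  }
  is_sensory <- vapply(series, function(s) s$index_name == "sensory_score",
                       logical(1))
  index_series <- series[!is_sensory]
  sensory_series <- series[is_sensory]

  # --- stage 2: kinetics ---------------------------------------------
  fits <- lapply(index_series, function(s)
    tryCatch(select_order(s),
             error = function(e) stop(sprintf("kinetics stage failed on %s at %g K: %s",
                                              s$index_name, s$temperature,
                                              conditionMessage(e)),
                                      call. = FALSE)))
  fit_df <- do.call(rbind, lapply(fits, function(f)
    data.frame(index_name = f$index_name, temperature = f$temperature,
               order = f$order, k = f$k, direction = f$direction,
               C0_hat = f$C0_hat, r_squared = f$r_squared)))
  paths$kinetic_fits <- file.path(out_dir, "kinetic_fits.csv")
  write_results(fit_df, paths$kinetic_fits)

  # --- stage 3: thermokinetics ---------------------------------------
  eyring_df <- NULL
  gibbs_df <- NULL
  for (ix in unique(fit_df$index_name)) {
    sub <- fit_df[fit_df$index_name == ix, ]
    if (length(unique(sub$temperature)) < 2L) next
    arr <- fit_arrhenius(sub$temperature, sub$k, constants = config$constants)
    rows <- lapply(seq_len(nrow(sub)), function(i)
      eyring_parameters(sub$temperature[i], sub$k[i], arr$Ea,
                        constants = config$constants,
                        convention = config$convention))
    eyring_df <- rbind(eyring_df, data.frame(
      index_name = ix,
      temperature = sub$temperature,
      k = sub$k,
      Ea = arr$Ea,
      dH = vapply(rows, `[[`, numeric(1), "dH"),
      dS = vapply(rows, `[[`, numeric(1), "dS"),
      dG = vapply(rows, `[[`, numeric(1), "dG"),
      convention = config$convention))
    gfit <- fit_gibbs_temperature(sub$temperature,
                                  vapply(rows, `[[`, numeric(1), "dG") / 1000)
    gibbs_df <- rbind(gibbs_df, data.frame(
      index_name = ix, slope = gfit$slope, intercept = gfit$intercept,
      r_squared = gfit$r_squared))
  }
  paths$eyring <- file.path(out_dir, "eyring.csv")
  write_results(eyring_df, paths$eyring)
  paths$gibbs <- file.path(out_dir, "gibbs_fits.csv")
  write_results(gibbs_df, paths$gibbs)

  # --- stage 4: sensory linkage + shelf life -------------------------
  shelf_df <- NULL
  sensory_df <- NULL
  skipped <- character()
  if (length(sensory_series) == 0L) {
    skipped <- c(skipped, "shelf_life: no sensory_score series in input")
    sk_log("run_pipeline: shelf-life stage skipped (no sensory series)")
  } else {
    sfits <- list()
    for (ix in unique(fit_df$index_name)) {
      idx <- index_series[vapply(index_series, function(s)
        s$index_name == ix, logical(1))]
      # pair only on arms where both the index and the score were observed
      temps_s <- vapply(sensory_series, `[[`, numeric(1), "temperature")
      idx <- idx[vapply(idx, function(s) s$temperature %in% temps_s,
                        logical(1))]
      if (length(idx) == 0L) next
      sfits[[ix]] <- tryCatch(
        fit_sensory_regression(sensory_series, idx),
        error = function(e) NULL)
    }
    sfits <- Filter(Negate(is.null), sfits)
    if (length(sfits) == 0L) {
      skipped <- c(skipped, "shelf_life: no index shares support with the sensory series")
    } else {
      sensory_df <- do.call(rbind, lapply(sfits, function(f)
        data.frame(index_name = f$index_name, slope = f$slope,
                   intercept = f$intercept, r_squared = f$r_squared)))
      paths$sensory <- file.path(out_dir, "sensory_fits.csv")
      write_results(sensory_df, paths$sensory)

      key <- select_key_index(sfits)
      gk <- gibbs_df[gibbs_df$index_name == key$index_name, ]
      C0 <- fit_df$C0_hat[fit_df$index_name == key$index_name][1L]
      dir_key <- fit_df$direction[fit_df$index_name == key$index_name][1L]
      model <- shelf_life_model(
        sensory = key,
        gibbs = structure(as.list(gk[c("slope", "intercept", "r_squared")]),
                          class = "gibbs_temp_fit"),
        C0 = C0, constants = config$constants,
        convention = config$convention, threshold = config$threshold,
        direction = dir_key)
      if (is.null(temperatures)) {
        temperatures <- sort(unique(fit_df$temperature))
      }
      shelf_df <- data.frame(
        index_name = key$index_name,
        temperature = temperatures,
        k = rate_from_gibbs(model, temperatures),
        SS0 = predict_sensory(model, 0, temperatures),
        shelf_life_days = vapply(temperatures, function(Tk)
          solve_shelf_life(model, Tk), numeric(1)))
      paths$shelf_life <- file.path(out_dir, "shelf_life.csv")
      write_results(shelf_df, paths$shelf_life)
    }
  }

  # --- manifest ------------------------------------------------------
  manifest <- list(
    tool = "shelfkin",
    version = as.character(utils::packageVersion("shelfkin")),
    convention = config$convention,
    threshold = config$threshold,
    seed = config$seed,
    synthetic = is.null(input),
    skipped = skipped,
    outputs = paths[setdiff(names(paths), "input")],
    input = paths$input,
    digests = as.list(tools::md5sum(unlist(paths)))
  )
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  sk_log("run_pipeline: wrote %d output file(s) to %s",
         length(paths) - 1L, out_dir)
  invisible(manifest)
}
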