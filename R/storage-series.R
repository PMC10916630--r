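#' Construct a storage series
#'
#' A `storage_series` is the unit of kinetic fitting: one quality index
#' measured repeatedly over storage time at one constant temperature.
#'
#' @param index_name Name of the quality index, e.g. `"CSR"`, `"viscosity"`,
#'   `"particle_size"`, `"sensory_score"`.
#' @param temperature Absolute storage temperature, K.
#' @param times Storage times, days; strictly increasing, first value >= 0.
#' @param values Measured index values at `times`; same length, all finite.
#'
#' @return An object of class `storage_series`.
#'
#' @examples
#' s <- storage_series("CSR", 298.15, c(0, 4, 8), c(0.82, 0.95, 1.10))
#' s
#' @export
storage_series <- function(index_name, temperature, times, values) {
  stopifnot(is.character(index_name), length(index_name) == 1L)
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("temperature must be a single positive value in kelvin", call. = FALSE)
  }
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("times and values must have the same length", call. = FALSE)
  }
  if (length(times) < 2L) {
    stop(sprintf("series '%s' at %g K has %d point(s); at least 2 required",
                 index_name, temperature, length(times)), call. = FALSE)
  }
  if (any(!is.finite(times)) || any(!is.finite(values))) {
    stop("times and values must all be finite", call. = FALSE)
  }
  if (times[1L] < 0 || any(diff(times) <= 0)) {
    stop("times must be strictly increasing and start at >= 0", call. = FALSE)
  }
  structure(
    list(index_name = index_name, temperature = temperature,
         times = times, values = values),
    class = "storage_series"
  )
}

#' @export
print.storage_series <- function(x, ...) {
  cat(sprintf("Storage series: %s at %.2f K, %d time points (%g-%g d)\n",
              x$index_name, x$temperature, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' @export
as.data.frame.storage_series <- function(x, ...) {
  data.frame(temperature_K = x$temperature, time_d = x$times,
             index = x$index_name, value = x$values,
             stringsAsFactors = FALSE)
}

#' Read storage series from CSV
#'
#' Reads a long-format CSV with header `temperature_K,time_d,index,value`
#' and returns one [storage_series()] per `(index, temperature_K)` group,
#' rows sorted by time. Grouping is exact on the numeric temperature value.
#'
#' @param path Path to a UTF-8, comma-separated file.
#' @param expected_header If `TRUE` (default) the header must match the
#'   canonical column names exactly.
#'
#' @return A named list of `storage_series`; names are
#'   `"<index>@<temperature>K"`.
#'
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' writeLines(c("temperature_K,time_d,index,value",
#'              "298.15,0,CSR,0.82", "298.15,4,CSR,0.95",
#'              "298.15,8,CSR,1.10"), tmp)
#' read_series_csv(tmp)
#' @export
read_series_csv <- function(path, expected_header = TRUE) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  canonical <- c("temperature_K", "time_d", "index", "value")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  if (expected_header) {
    missing <- setdiff(canonical, names(df))
    if (length(missing) > 0L) {
      stop(sprintf("missing or renamed column(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    df <- df[canonical]
  }
  for (col in c("temperature_K", "time_d", "value")) {
    raw <- df[[col]]
    if (any(!nzchar(trimws(raw)))) {
      bad <- which(!nzchar(trimws(raw)))[1L]
      stop(sprintf("empty '%s' cell at data row %d; missing values are not imputed",
                   col, bad), call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(raw))
    if (any(is.na(num))) {
      bad <- which(is.na(num))[1L]
      stop(sprintf("non-numeric '%s' cell at data row %d: '%s'",
                   col, bad, raw[bad]), call. = FALSE)
    }
    df[[col]] <- num
  }
  key <- paste0(df$index, "@", format(df$temperature_K, trim = TRUE), "K")
  groups <- split(df, key)
  sk_log("read_series_csv: %d rows, %d series group(s) from %s",
         nrow(df), length(groups), path)
  out <- lapply(groups, function(g) {
    g <- g[order(g$time_d), , drop = FALSE]
    if (nrow(g) < 2L) {
      stop(sprintf("group (%s, %g K) has %d row(s); at least 2 required",
                   g$index[1L], g$temperature_K[1L], nrow(g)), call. = FALSE)
    }
    storage_series(g$index[1L], g$temperature_K[1L], g$time_d, g$value)
  })
  out[order(names(out))]
}

#' Write result records to CSV
#'
#' Writes a list of flat records (or a data frame) as CSV with a
#' deterministic column order and rows sorted by `index_name` then
#' `temperature` where those columns exist. Floats are serialized with 10
#' significant digits so that write/read round-trips are lossless well
#' beyond measurement precision.
#'
#' @param records A data frame, or a list of named lists sharing one field set.
#' @param path Output file path.
#' @return Invisibly, the data frame written.
#' @export
write_results <- function(records, path) {
  if (!is.data.frame(records)) {
    if (length(records) > 0L) {
      fields <- names(records[[1L]])
      same <- vapply(records, function(r) identical(names(r), fields), logical(1))
      if (!all(same)) {
        stop("all records must share one flat field set", call. = FALSE)
      }
      records <- do.call(rbind, lapply(records, function(r)
        as.data.frame(r, stringsAsFactors = FALSE)))
    } else {
      records <- data.frame()
    }
  }
  if (nrow(records) > 0L) {
    ord <- seq_len(nrow(records))
    if (all(c("index_name", "temperature") %in% names(records))) {
      ord <- order(records$index_name, records$temperature)
    } else if ("index_name" %in% names(records)) {
      ord <- order(records$index_name)
    }
    records <- records[ord, , drop = FALSE]
  }
  fmt <- records
  for (col in names(fmt)) {
    if (is.numeric(fmt[[col]])) {
      fmt[[col]] <- trimws(formatC(fmt[[col]], digits = 10, format = "g"))
    }
  }
  ok <- tryCatch({
    utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop(sprintf("cannot write results to '%s': %s", path,
                 conditionMessage(ok)), call. = FALSE)
  }
  sk_log("write_results: %d row(s) -> %s", nrow(records), path)
  invisible(records)
}

# stderr logger; silence with options(shelfkin.verbose = FALSE)
sk_log <- function(fmt, ...) {
  if (isTRUE(getOption("shelfkin.verbose", TRUE))) {
    message(sprintf(paste0("[shelfkin] ", fmt), ...))
  }
  invisible(NULL)
}
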