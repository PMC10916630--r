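# shared fixtures built in code

options(shelfkin.verbose = FALSE)

# noiseless first-order series on the accelerated-storage grid
exact_exp_series <- function(k = 0.0367, C0 = 0.82, direction = 1,
                             temperature = 298.15, times = seq(0, 40, by = 4),
                             index_name = "CSR") {
  storage_series(index_name, temperature, times,
                 C0 * exp(direction * k * times))
}

# write a long-format series CSV and return its path
write_series_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# published Table-2-style reference rows used across thermo tests:
# per index x temperature, the printed (k, Ea) inputs and (dH, dS, dG) outputs
reference_eyring_rows <- function() {
  data.frame(
    index_name = rep(c("CSR", "particle_size", "viscosity"), each = 3L),
    temperature = rep(c(298.15, 308.15, 318.15), 3L),
    k = c(0.0367, 0.0678, 0.1013, 0.0158, 0.0270, 0.0420,
          0.0630, 0.0112, 0.0168),
    Ea = c(40800, 40800, 40800, 38580, 38580, 38560, 10560, 10560, 10560),
    dH_kJ = c(38.32, 38.24, 38.15, 36.10, 36.02, 35.91, 8.08, 8.00, 7.91),
    dS = c(-143.85, -143.47, -144.56, -158.31, -158.33, -158.92,
           -240.79, -256.57, -254.54),
    dG_kJ = c(81.21, 82.45, 84.15, 83.30, 84.81, 86.47, 79.87, 87.06, 88.90)
  )
}
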