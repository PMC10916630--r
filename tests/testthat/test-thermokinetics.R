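test_that("Arrhenius fit recovers self-consistent rates exactly", {
  Tk <- c(298.15, 308.15, 318.15)
  A0 <- 1e10
  Ea <- 50000
  k <- A0 * exp(-Ea / (8.314 * Tk))
  fit <- fit_arrhenius(Tk, k)
  expect_equal(fit$Ea, Ea, tolerance = 1e-9)
  expect_equal(fit$A0, A0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # temperature-independent rates carry no activation barrier
  expect_equal(fit_arrhenius(c(298.15, 318.15), c(0.05, 0.05))$Ea, 0,
               tolerance = 1e-9)
})

test_that("Arrhenius fit on the published CSR rates matches an OLS oracle", {
  Tk <- c(298.15, 308.15, 318.15)
  k <- c(0.0367, 0.0678, 0.1013)
  # independent oracle: closed-form OLS slope of ln k on 1/T
  x <- 1 / Tk
  y <- log(k)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  fit <- fit_arrhenius(Tk, k)
  expect_equal(fit$Ea, -slope * 8.314, tolerance = 1e-9)
  # the published 40.8 kJ/mol is ~2% above the OLS value; both near 40 kJ/mol
  expect_equal(fit$Ea, 40800, tolerance = 0.05)
})

test_that("duplicate temperatures collapse to geometric means with a warning", {
  expect_warning(
    fit <- fit_arrhenius(c(298.15, 298.15, 318.15), c(0.03, 0.05, 0.10)),
    "geometric")
  expect_warning(
    ref <- fit_arrhenius(c(298.15, 318.15), c(sqrt(0.03 * 0.05), 0.10)),
    NA)
  expect_equal(fit$Ea, ref$Ea, tolerance = 1e-12)
  expect_error(fit_arrhenius(c(298.15, 318.15), c(0, 0.1)), "> 0")
})

test_that("Eyring parameters reproduce every published table row", {
  rows <- reference_eyring_rows()
  for (i in seq_len(nrow(rows))) {
    e <- eyring_parameters(rows$temperature[i], rows$k[i], rows$Ea[i],
                           convention = "per_day_numeric")
    expect_equal(e$dH / 1000, rows$dH_kJ[i], tolerance = 0.01 / rows$dH_kJ[i])
    expect_equal(e$dS, rows$dS[i], tolerance = 0.01 / abs(rows$dS[i]))
    expect_equal(e$dG / 1000, rows$dG_kJ[i], tolerance = 0.01 / rows$dG_kJ[i])
  }
})

test_that("activation enthalpy is positive for all reference rows", {
  # endothermic storage degradation: dH* > 0 across indices and temperatures
  rows <- reference_eyring_rows()
  for (i in seq_len(nrow(rows))) {
    e <- eyring_parameters(rows$temperature[i], rows$k[i], rows$Ea[i])
    expect_gt(e$dH, 0)
  }
  # limit case: Ea = RT makes dH* exactly zero
  expect_equal(eyring_parameters(300, 0.05, 8.314 * 300)$dH, 0,
               tolerance = 1e-9)
})

test_that("Eyring rows round-trip back to the rate constant", {
  rows <- reference_eyring_rows()
  for (conv in c("per_day_numeric", "per_second_SI")) {
    for (i in seq_len(nrow(rows))) {
      e <- eyring_parameters(rows$temperature[i], rows$k[i], rows$Ea[i],
                             convention = conv)
      expect_equal(eyring_rate(e), rows$k[i], tolerance = 1e-9)
      # the two dG paths agree: dH - T dS == -RT ln(k' h / (kb T))
      kp <- if (conv == "per_second_SI") rows$k[i] / 86400 else rows$k[i]
      dG_direct <- -8.314 * rows$temperature[i] *
        log(kp * 6.626e-34 / (1.38e-23 * rows$temperature[i]))
      expect_equal(e$dG, dG_direct, tolerance = 1e-9)
    }
  }
})

test_that("the SI rate convention shifts dS* by -R ln 86400", {
  day <- eyring_parameters(298.15, 0.0367, 40800,
                           convention = "per_day_numeric")
  si <- eyring_parameters(298.15, 0.0367, 40800,
                          convention = "per_second_SI")
  expect_equal(si$dS - day$dS, -8.314 * log(86400), tolerance = 1e-9)
  expect_equal(si$dH, day$dH)
})

test_that("Gibbs-temperature regression reproduces the published equations", {
  rows <- reference_eyring_rows()
  pub <- data.frame(index_name = c("CSR", "particle_size", "viscosity"),
                    slope = c(0.1467, 0.1587, 0.4513),
                    intercept = c(37.398, 35.964, -53.788),
                    r2 = c(0.9918, 0.9991, 0.8951))
  for (i in seq_len(nrow(pub))) {
    sub <- rows[rows$index_name == pub$index_name[i], ]
    fit <- fit_gibbs_temperature(sub$temperature, sub$dG_kJ)
    expect_equal(fit$slope, pub$slope[i], tolerance = 0.01)
    expect_equal(fit$r_squared, pub$r2[i], tolerance = 0.01)
  }
  # exactly collinear points
  perfect <- fit_gibbs_temperature(c(300, 310, 320), 0.15 * c(300, 310, 320) + 37)
  expect_equal(perfect$r_squared, 1, tolerance = 1e-12)
  expect_equal(perfect$slope, 0.15, tolerance = 1e-12)
  expect_error(fit_gibbs_temperature(c(300, 300), c(80, 81)), "distinct")
})

test_that("Arrhenius and Eyring stages are mutually consistent", {
  # rates generated from a chosen (A0, Ea) recover Ea, and dH* falls
  # linearly in T with slope -R
  Tk <- seq(295, 325, by = 5)
  Ea <- 42000
  k <- 5e9 * exp(-Ea / (8.314 * Tk))
  fit <- fit_arrhenius(Tk, k)
  expect_equal(fit$Ea, Ea, tolerance = 1e-9)
  dH <- vapply(seq_along(Tk), function(i)
    eyring_parameters(Tk[i], k[i], fit$Ea)$dH, numeric(1))
  slopes <- diff(dH) / diff(Tk)
  expect_equal(slopes, rep(-8.314, length(slopes)), tolerance = 1e-9)
})
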