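# published CSR model pieces reused across blocks
csr_model <- function(threshold = 80, C0 = 0.82) {
  shelf_life_model(
    sensory = structure(list(index_name = "CSR", slope = -9.6927,
                             intercept = 96.131, r_squared = 0.9868),
                        class = "sensory_fit"),
    gibbs = structure(list(slope = 0.1467, intercept = 37.398,
                           r_squared = 0.9918),
                      class = "gibbs_temp_fit"),
    C0 = C0, threshold = threshold)
}

test_that("sensory regression recovers an exact linear linkage", {
  t <- seq(0, 40, by = 4)
  pooled_csr <- lapply(c(298.15, 308.15, 318.15), function(Tk)
    exact_exp_series(k = 0.04 * Tk / 300, temperature = Tk, times = t))
  pooled_ss <- lapply(pooled_csr, function(s)
    storage_series("sensory_score", s$temperature, s$times,
                   -9.6927 * s$values + 96.131))
  fit <- fit_sensory_regression(pooled_ss, pooled_csr)
  expect_equal(fit$slope, -9.6927, tolerance = 1e-9)
  expect_equal(fit$intercept, 96.131, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$index_name, "CSR")
})

test_that("constant sensory score gives zero slope and zero r-squared", {
  t <- 0:5
  idx <- storage_series("CSR", 298.15, t, 0.82 * exp(0.05 * t))
  ss <- storage_series("sensory_score", 298.15, t, rep(90, length(t)))
  fit <- fit_sensory_regression(ss, idx)
  expect_equal(fit$slope, 0)
  expect_equal(fit$r_squared, 0)
  expect_equal(fit$intercept, 90)
})

test_that("noisy sensory linkage is recovered within 5% at n = 40", {
  set.seed(40)
  eta <- runif(40, 3, 6)
  ss_vals <- 10.322 * eta - 28.007 + rnorm(40, 0, 0.5)
  # pack as series on a shared support across two temperatures
  t <- seq(0, 19)
  idx <- list(storage_series("viscosity", 298.15, t, eta[1:20]),
              storage_series("viscosity", 308.15, t, eta[21:40]))
  ss <- list(storage_series("sensory_score", 298.15, t, ss_vals[1:20]),
             storage_series("sensory_score", 308.15, t, ss_vals[21:40]))
  fit <- fit_sensory_regression(ss, idx)
  expect_equal(fit$slope, 10.322, tolerance = 0.05)
})

test_that("mismatched sensory/index support is rejected with the points listed", {
  idx <- storage_series("CSR", 298.15, c(0, 4, 8), c(0.8, 0.9, 1.0))
  ss <- storage_series("sensory_score", 298.15, c(0, 4, 12), c(95, 92, 88))
  expect_error(fit_sensory_regression(ss, idx), "298.15 12")
})

test_that("key-index selection maximizes r-squared with a stable tie rule", {
  mk <- function(name, r2) structure(
    list(index_name = name, slope = -1, intercept = 90, r_squared = r2),
    class = "sensory_fit")
  fits <- list(mk("viscosity", 0.9558), mk("CSR", 0.9868),
               mk("particle_size", 0.9796))
  expect_equal(select_key_index(fits)$index_name, "CSR")
  expect_equal(select_key_index(fits[1])$index_name, "viscosity")
  tie <- list(mk("b", 0.9), mk("a", 0.9))
  expect_equal(select_key_index(tie)$index_name, "a")
  expect_error(select_key_index(list()), "no sensory fits")
})

test_that("rate interpolated from the Gibbs regression matches the closed form", {
  m <- csr_model()
  # independent oracle: direct evaluation of (kb T / h) exp(-dG/(RT))
  oracle <- function(Tk) {
    dG <- 1000 * (0.1467 * Tk + 37.398)
    (1.38e-23 * Tk / 6.626e-34) * exp(-dG / (8.314 * Tk))
  }
  expect_equal(rate_from_gibbs(m, 298.15), oracle(298.15), tolerance = 1e-12)
  expect_equal(rate_from_gibbs(m, 298.15), 0.0378, tolerance = 0.005)
  # consistent with the published fitted rate up to the regression rounding
  expect_equal(rate_from_gibbs(m, 298.15), 0.0367, tolerance = 0.05)
  # strictly increasing in T over the storage range
  grid <- rate_from_gibbs(m, seq(298, 328, by = 0.5))
  expect_true(all(diff(grid) > 0))
})

test_that("no-barrier limit of the interpolated rate is kb T / h", {
  m <- csr_model()
  m$gibbs$slope <- 0
  m$gibbs$intercept <- 0
  expect_equal(rate_from_gibbs(m, 300), 1.38e-23 * 300 / 6.626e-34,
               tolerance = 1e-12)
})

test_that("sensory prediction has the right intercept and monotonicity", {
  m <- csr_model()
  expect_equal(predict_sensory(m, 0, 298.15), 96.131 - 9.6927 * 0.82,
               tolerance = 1e-12)
  tt <- seq(0, 60, by = 1)
  ss <- predict_sensory(m, tt, 298.15)
  expect_true(all(diff(ss) < 0))
})

test_that("shelf life solves the threshold crossing in closed form", {
  m <- csr_model()
  t80 <- solve_shelf_life(m, 298.15)
  expect_equal(t80, 18.7, tolerance = 0.005)
  # round trip: the predicted score at the solved time is the threshold
  expect_equal(predict_sensory(m, t80, 298.15), 80, tolerance = 1e-9)

  # numeric inversion oracle for the same crossing
  root <- uniroot(function(t) predict_sensory(m, t, 298.15) - 80,
                  c(0, 100), tol = 1e-12)$root
  expect_equal(t80, root, tolerance = 1e-9)

  # threshold at the initial score: zero shelf life
  ss0 <- predict_sensory(m, 0, 298.15)
  expect_equal(solve_shelf_life(csr_model(threshold = ss0), 298.15), 0)

  # hotter storage fails sooner
  expect_lt(solve_shelf_life(m, 318.15), solve_shelf_life(m, 298.15))
})

test_that("a decaying key index with positive sensory slope is solvable", {
  m <- shelf_life_model(
    sensory = structure(list(index_name = "viscosity", slope = 10.322,
                             intercept = -28.007), class = "sensory_fit"),
    gibbs = structure(list(slope = 0.4513, intercept = -53.788),
                      class = "gibbs_temp_fit"),
    C0 = 5.82, threshold = 25, direction = -1)
  t_s <- solve_shelf_life(m, 298.15)
  expect_gt(t_s, 0)
  expect_equal(predict_sensory(m, t_s, 298.15), 25, tolerance = 1e-9)
})

test_that("model construction rejects unreachable thresholds", {
  expect_error(csr_model(threshold = 95), "below the initial score")
  expect_error(shelf_life_model(
    sensory = structure(list(index_name = "CSR", slope = 2, intercept = 90),
                        class = "sensory_fit"),
    gibbs = structure(list(slope = 0.1, intercept = 30),
                      class = "gibbs_temp_fit"),
    C0 = 1), "negative sensory slope")
})

test_that("validation statistics match hand arithmetic", {
  v <- validate_predictions(c(90, 120, 150), c(80, 110, 160), k_pred = 1)
  expect_equal(v$Se, sqrt(300), tolerance = 1e-12)
  expect_equal(v$Ve, 100 * sqrt(300) / 120, tolerance = 1e-12)
  expect_true(v$passes)

  exact <- validate_predictions(c(10, 20, 30, 40), c(10, 20, 30, 40), 1)
  expect_equal(exact$Se, 0)
  expect_equal(exact$Ve, 0)

  expect_error(validate_predictions(c(1, 2, 3), c(1, 2, 3), k_pred = 2),
               "degrees of freedom")
  expect_error(validate_predictions(c(1, 2, 3), c(1, 2), 1), "equal length")
})
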