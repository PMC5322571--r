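test_that("anisotropy matches the polarized-intensity formula", {
  expect_equal(anisotropy(1, 1), 0)        # isotropic limit
  expect_equal(anisotropy(2, 1), 0.25)
  expect_equal(anisotropy(5, 0), 1)        # fully polarized limit
  expect_equal(anisotropy(2, 1, g = 2), (2 - 2) / (2 + 4))
  expect_error(anisotropy(0, 0), "positive")
})

test_that("noiseless isotherm fits recover the generator exactly", {
  Tg <- c(1, 10, 50, 100, 200, 500, 1000, 2000)
  ser <- simulate_titration(Kd = 200, constant = 0.05, T_grid = Tg,
                            noise_sd = 0, seed = 1)
  fit <- fit_isotherm(ser)
  expect_true(fit$converged)
  expect_equal(fit$Kd, 200, tolerance = 1e-6)
  expect_equal(fit$amplitude, 0.05, tolerance = 1e-6)
  # on the fitted curve, the response at T = Kd is exactly half-saturation
  expect_equal(predict(fit, fit$Kd), fit$amplitude / 2)

  expect_error(fit_isotherm(titration_series(c(0, 10, 10, 20), rep(0.1, 4))),
               "4 distinct")
})

test_that("degenerate all-zero titrations are flagged, not thrown", {
  ser <- titration_series(c(0, 10, 100, 1000, 2000), rep(0, 5))
  fit <- fit_isotherm(ser)
  expect_false(fit$converged)
  expect_true(is.na(fit$amplitude) || abs(fit$amplitude) < 1e-6)
})

test_that("fits are invariant to the order of titration points", {
  ser <- simulate_titration(150, 0.04, c(0, 5, 20, 80, 300, 1200, 2000),
                            noise_sd = 0.002, n_replicates = 2, seed = 9)
  df <- as.data.frame(ser)
  set.seed(10)
  shuf <- df[sample(nrow(df)), ]
  f1 <- fit_isotherm(titration_series(df$concentration, df$response))
  f2 <- fit_isotherm(titration_series(shuf$concentration, shuf$response))
  expect_equal(f1$Kd, f2$Kd, tolerance = 1e-6)
  expect_equal(f1$amplitude, f2$amplitude, tolerance = 1e-6)
})

test_that("the fitted curve is saturating and monotone", {
  ser <- simulate_titration(207, 0.05, c(1, 10, 50, 100, 200, 500, 2000),
                            noise_sd = 0.001, n_replicates = 2, seed = 11)
  fit <- fit_isotherm(ser)
  Tg <- seq(0, 5000, by = 50)
  y <- predict(fit, Tg)
  expect_true(all(diff(y) > 0))
  expect_true(all(y <= fit$amplitude))
})

test_that("Kd estimation error shrinks with the noise level", {
  Tg <- c(0, 1, 10, 50, 100, 200, 500, 1000, 2000)
  med_err <- vapply(c(0.0005, 0.0025, 0.01), function(ns) {
    errs <- vapply(1:25, function(s) {
      f <- fit_isotherm(simulate_titration(207, 0.05, Tg, ns,
                                           n_replicates = 4, seed = s))
      abs(f$Kd - 207) / 207
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) > 0))
})

test_that("APCE depletion responses derive from ratioed peak heights", {
  pts <- data.frame(concentration = c(0, 0, 50, 200, 1000),
                    aptamer_peak = c(10, 10.2, 8, 6, 5.2),
                    standard_peak = c(10, 10, 10, 10, 10))
  ser <- apce_response(pts)
  expect_equal(attr(ser, "assay"), "APCE")
  r0 <- mean(c(1.0, 1.02))
  expect_equal(ser$response, r0 - pts$aptamer_peak / pts$standard_peak)
  # monotone-decreasing ratios give non-negative responses past T = 0
  expect_true(all(ser$response[ser$concentration > 0] >= 0))
  # saturating depletion approaches ratio(0) - ratio(inf)
  pts2 <- data.frame(concentration = c(0, 1e6),
                     aptamer_peak = c(1, 0.5), standard_peak = c(1, 1))
  expect_equal(apce_response(pts2)$response[2], 0.5)
  # constant ratios give an all-zero response
  pts3 <- data.frame(concentration = c(0, 10, 100),
                     aptamer_peak = 2, standard_peak = 2)
  expect_true(all(apce_response(pts3)$response == 0))

  expect_error(apce_response(pts[pts$concentration > 0, ]),
               "zero-concentration")
  expect_error(apce_response(transform(pts, standard_peak = 0)), "positive")
  # raw-ratio convention passes ratios through unchanged
  expect_equal(apce_response(pts, convention = "fit_raw_ratio")$response,
               pts$aptamer_peak / pts$standard_peak)
})

test_that("simulated titrations are seed-deterministic", {
  a <- simulate_titration(100, 1, c(1, 10, 100), 0.1, 3, seed = 42)
  b <- simulate_titration(100, 1, c(1, 10, 100), 0.1, 3, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c0 <- simulate_titration(100, 1, c(1, 10, 100), 0, 1, seed = 1)
  expect_equal(c0$response, 1 * c(1, 10, 100) / (100 + c(1, 10, 100)))
  expect_error(simulate_titration(-1, 1, 1:5), "Kd must be")
})

test_that("titration CSVs in both assay layouts are parsed", {
  f <- tempfile(fileext = ".csv")
  df <- data.frame(assay = "FA",
                   concentration_U_per_mL = c(0, 0, 100, 500, 2000),
                   replicate = c(1, 2, 1, 1, 1),
                   I_parallel = c(1.00, 1.00, 1.10, 1.20, 1.25),
                   I_perpendicular = c(1.00, 1.00, 1.00, 1.00, 1.00))
  write.csv(df, f, row.names = FALSE)
  ser <- read_titration_csv(f)
  expect_equal(attr(ser, "assay"), "FA")
  expect_equal(ser$response[1:2], c(0, 0))  # delta-r relative to T = 0
  expect_true(all(diff(ser$response[2:5]) > 0))

  df2 <- data.frame(assay = "APCE",
                    concentration_U_per_mL = c(0, 100, 1000, 2000),
                    replicate = 1,
                    aptamer_peak = c(10, 8, 6, 5.5),
                    standard_peak = 10)
  write.csv(df2, f, row.names = FALSE)
  ser2 <- read_titration_csv(f)
  expect_equal(attr(ser2, "assay"), "APCE")
  expect_equal(ser2$response, 1 - df2$aptamer_peak / 10)

  write.csv(data.frame(concentration_U_per_mL = 1, x = 2), f, row.names = FALSE)
  expect_error(read_titration_csv(f), "unrecognized")
})
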