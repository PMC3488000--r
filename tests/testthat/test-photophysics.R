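test_that("trapezoidal integration matches hand geometry and a finer-grid oracle", {
  wl <- 470:600
  expect_equal(integrate_emission(emission_spectrum(wl, rep(1, 131))), 130)

  # triangle of height 10, base 20 nm centered at 500
  tri <- pmax(0, 10 * (1 - abs(wl - 500) / 10))
  expect_equal(integrate_emission(emission_spectrum(wl, tri)), 100,
               tolerance = 1e-12)

  # refinement oracle: 10x finer Riemann sum of the analytic peak shape
  shape <- function(l) exp(-(l - 495)^2 / (2 * ifelse(l <= 495, 12, 19.2)^2))
  coarse <- integrate_emission(emission_spectrum(wl, shape(wl)))
  fine_grid <- seq(470, 600, by = 0.1)
  fine <- sum(shape(fine_grid[-1] - 0.05)) * 0.1
  expect_equal(coarse, fine, tolerance = 1e-3)

  expect_error(integrate_emission(emission_spectrum(wl, tri), c(460, 600)),
               "outside the scan")
})

test_that("quantum yield identity, linearity and homogeneity hold", {
  series <- tibble::tibble(integrated_emission = c(100, 200, 300),
                           absorbance_450 = c(0.1, 0.2, 0.3))
  expect_equal(quantum_yield(series, series)$value, 0.27)
  expect_equal(quantum_yield(series, series)$sd, 0)

  doubled <- dplyr::mutate(series, integrated_emission = 2 * integrated_emission)
  expect_equal(quantum_yield(doubled, series)$value, 0.54)

  # scaling all sample emissions by k scales the estimate by k
  for (k in c(0.3, 1.7, 5)) {
    scaled <- dplyr::mutate(series, integrated_emission = k * integrated_emission)
    expect_equal(quantum_yield(scaled, series)$value, k * 0.27)
  }
  # both aggregation methods agree on proportional data
  expect_equal(quantum_yield(series, series, method = "slope")$value, 0.27)
})

test_that("quantum yield validates its inputs", {
  series <- tibble::tibble(integrated_emission = 1, absorbance_450 = 1)
  bad <- tibble::tibble(integrated_emission = 1, absorbance_450 = 0)
  expect_error(quantum_yield(bad, series), "non-positive absorbance")
  expect_error(quantum_yield(series[0, ], series), "empty")
  expect_error(quantum_yield(series, series, standard_qy = 0), "\\(0, 1\\]")
})

test_that("quantum yield is recovered from a noisy synthetic series", {
  ph <- generate_photophysics_series(true_qy = 0.30, true_f_holo = 0.49,
                                     noise_fraction = 0.01, seed = 81)
  est <- quantum_yield(ph$sample, ph$standard)
  expect_equal(est$value, 0.30, tolerance = 0.01 / 0.30)
  expect_gt(est$sd, 0)
})

test_that("Beer-Lambert holoprotein concentration is exact arithmetic", {
  expect_equal(holoprotein_concentration(0.125, 12500, 1), 10e-6)
  expect_equal(holoprotein_concentration(0), 0)
  expect_equal(holoprotein_concentration(0.25, path_length_cm = 0.5), 40e-6)
  expect_error(holoprotein_concentration(0.1, epsilon = -1), "positive")
  expect_error(holoprotein_concentration(-0.1), ">= 0")
})

test_that("holoprotein fraction clamps marginal excess and rejects large excess", {
  expect_equal(holo_fraction(1e-5, 1e-5), 1)
  expect_warning(f <- holo_fraction(1.02e-5, 1e-5), "clamped")
  expect_equal(f, 1)
  expect_error(holo_fraction(1.2e-5, 1e-5), "inconsistent")
  expect_error(holo_fraction(1e-5, 0), "> 0")
})

test_that("holoprotein fraction is recovered from noisy replicates", {
  fs <- vapply(1:10, function(i) {
    ph <- generate_photophysics_series(true_qy = 0.17, true_f_holo = 0.33,
                                       noise_fraction = 0.02, seed = 500 + i)
    mean(holo_fraction(holoprotein_concentration(ph$sample$absorbance_450),
                       ph$sample$concentration))
  }, numeric(1))
  expect_equal(mean(fs), 0.33, tolerance = 0.01 / 0.33)
})

test_that("fold enhancement reproduces the published brightness ratios", {
  qy <- fold_with_error(0.30, 0.17, 0.01, 0)
  expect_equal(qy$value, 0.30 / 0.17)
  expect_equal(format_fold(qy), 1.8)
  expect_equal(format_fold(fold_with_error(0.24, 0.17)), 1.4)
  expect_equal(format_fold(fold_with_error(0.49, 0.33)), 1.5)
  expect_equal(format_fold(fold_with_error(0.45, 0.33)), 1.4)
})

test_that("fold propagation is scale-invariant with delta-method sd", {
  f1 <- fold_with_error(0.3, 0.2, 0.01, 0.02)
  f2 <- fold_with_error(3, 2, 0.1, 0.2)
  expect_equal(f1$value, f2$value)
  expect_equal(f1$sd, f2$sd)
  expect_equal(f1$sd, f1$value * sqrt((0.01 / 0.3)^2 + (0.02 / 0.2)^2))
  z <- fold_with_error(5, 5)
  expect_equal(z$value, 1)
  expect_equal(z$sd, 0)
  expect_error(fold_with_error(1, 0), "positive")
})
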