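test_that("a single exact Lorentzian is recovered with its closed-form area", {
  wn <- default_wavenumbers()
  s <- raman_spectrum(wn, lorentzian(wn, 1440, 100, 8), 532)
  f <- fit_window(s, c(1340, 1540), 1)
  expect_equal(f$peaks$area[1], pi * 100 * 8, tolerance = 0.005)
  expect_equal(f$peaks$center[1], 1440, tolerance = 0.1)
  expect_equal(f$peaks$hwhm[1], 8, tolerance = 0.05)
  expect_gt(f$explained_area_fraction, 0.99)
})

test_that("overlapping components match the numeric-integration oracle", {
  wn <- default_wavenumbers()
  y <- lorentzian(wn, 1440, 100, 8) + lorentzian(wn, 1460, 70, 8)
  s <- raman_spectrum(wn, y, 532)
  f <- fit_window(s, c(1380, 1540), 2, init = c(1440, 1460),
                  quality_warning = FALSE)
  oracle <- c(numeric_lorentz_area(1440, 100, 8),
              numeric_lorentz_area(1460, 70, 8))
  expect_equal(f$peaks$area, oracle, tolerance = 0.01)
})

test_that("explained-area quality gate warns below 99.9% but still returns", {
  wn <- default_wavenumbers()
  set.seed(9)
  # a second unmodelled band makes the single-component fit incomplete
  y <- lorentzian(wn, 1440, 100, 8) + lorentzian(wn, 1480, 30, 8)
  s <- raman_spectrum(wn, y, 532)
  expect_warning(f <- fit_window(s, c(1380, 1510), 1, init = 1440), "99.9")
  expect_lt(f$explained_area_fraction, 0.999)
  expect_true(f$converged)
})

test_that("degenerate windows raise fit errors", {
  wn <- default_wavenumbers()
  s <- raman_spectrum(wn, rep(0, length(wn)), 532)
  expect_error(fit_window(s, c(1380, 1500), 1), "degenerate")
  s2 <- raman_spectrum(wn, lorentzian(wn, 1440, 10, 8), 532)
  expect_error(fit_window(s2, c(5000, 5200), 1), "outside")
})

test_that("noise-free generator ratios match the analytic contract end to end", {
  for (fa in standard_registry()) {
    s <- simulate_standard(fa, 532, noise_sd = 0)
    r <- quiet_ratios(s, noise_sd = 1e-9)
    expect_equal(r$r1650_1440, 7.3 * fa$n_double_bonds / fa$n_ch2,
                 tolerance = 0.01, info = fa$code)
  }
})

test_that("ratios are invariant to positive rescaling of the spectrum", {
  s <- simulate_standard(oleic(), 532, noise_sd = 0)
  r1 <- quiet_ratios(s, noise_sd = 1e-9)
  s$intensity <- s$intensity * 37.5
  r2 <- quiet_ratios(s, noise_sd = 1e-9)
  expect_equal(r2$r1650_1440, r1$r1650_1440, tolerance = 1e-6)
  expect_equal(r2$r3003_1440, r1$r3003_1440, tolerance = 1e-4)
})

test_that("saturated standards read zero on both unsaturation ratios", {
  s <- simulate_standard(registry_fa("C18:0"), 532, noise_sd = 0.5, seed = 10)
  r <- quiet_ratios(s, noise_sd = 0.5)
  expect_identical(r$r1650_1440, 0)
  expect_identical(r$r3003_1440, 0)
})

test_that("the two unsaturation ratios are concordant across standards", {
  reg <- standard_registry()
  rs <- t(vapply(reg, function(fa) {
    r <- quiet_ratios(simulate_standard(fa, 532, noise_sd = 0.5,
                                        seed = fa$n_carbons),
                      noise_sd = 0.5)
    c(r$r1650_1440, r$r3003_1440)
  }, numeric(2)))
  fit <- stats::lm(rs[, 2] ~ rs[, 1])
  expect_gt(stats::coef(fit)[2], 0)
  expect_gt(summary(fit)$r.squared, 0.95)
})

test_that("contaminated spectra are refused unless explicitly overridden", {
  s <- subtract_background(
    simulate_cell(cell_profile(protein = 1), 75, noise_sd = 0.5, seed = 11))
  expect_error(intensity_ratios(s, noise_sd = 0.5), "protein")
  expect_warning(r <- intensity_ratios(s, noise_sd = 0.5,
                                       allow_contaminated = TRUE),
                 "contamination")
  expect_gt(r$r1650_1440, 0)
})

test_that("a missing 1440 band is an undefined-ratio error", {
  wn <- default_wavenumbers()
  s <- raman_spectrum(wn, lorentzian(wn, 1650, 50, 8), 532)
  expect_error(intensity_ratios(s, noise_sd = 0.5, protein_check = FALSE),
               "1440")
})
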