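make_spec <- function(y, excitation = 532) {
  raman_spectrum(default_wavenumbers(), y, excitation)
}

test_that("moving average of a constant spectrum subtracts to zero", {
  s <- make_spec(rep(7.5, length(default_wavenumbers())))
  out <- subtract_background(s)
  expect_equal(out$intensity, rep(0, length(s$wavenumber)))
})

test_that("a linear ramp is removed exactly away from the edges", {
  wn <- default_wavenumbers()
  s <- make_spec(0.1 * wn + 40)
  out <- subtract_background(s, 300)
  k <- 101  # 300 cm^-1 at 3 cm^-1 steps, rounded to odd
  interior <- (k + 1):(length(wn) - k)
  expect_equal(max(abs(out$intensity[interior])), 0, tolerance = 1e-9)
})

test_that("background subtraction is linear in the spectrum", {
  wn <- default_wavenumbers()
  set.seed(3)
  y1 <- lorentzian(wn, 1440, 100, 8) + 50 * exp(-wn / 900)
  y2 <- lorentzian(wn, 1650, 60, 8) + 0.02 * wn
  bg <- function(y) subtract_background(make_spec(y))$intensity
  expect_equal(bg(2 * y1 + 3 * y2), 2 * bg(y1) + 3 * bg(y2), tolerance = 1e-10)
})

test_that("band area survives subtraction over a slow background within 5%", {
  wn <- default_wavenumbers()
  truth <- lorentzian_area(100, 8)
  y <- lorentzian(wn, 1440, 100, 8) + 300 * exp(-wn / 1500) + 20
  f <- fit_window(subtract_background(make_spec(y)), c(1380, 1500), 1,
                  init = 1440, quality_warning = FALSE)
  expect_equal(f$peaks$area[1], truth, tolerance = 0.05)
})

test_that("oversized and undersized windows are rejected", {
  s <- make_spec(rep(1, length(default_wavenumbers())))
  expect_error(subtract_background(s, 5000), "exceeds")
  expect_error(subtract_background(s, 5), "3 grid steps")
})

test_that("protein screen flags the generator's protein bands and only those", {
  clean <- subtract_background(simulate_cell(cell_profile(), 75, noise_sd = 0.5, seed = 1))
  pr <- protein_screen(clean, noise_sd = 0.5)
  expect_false(pr$protein_contaminated)
  expect_length(pr$protein_bands, 0)

  dirty <- subtract_background(
    simulate_cell(cell_profile(protein = 1), 75, noise_sd = 0.5, seed = 1))
  pr2 <- protein_screen(dirty, noise_sd = 0.5)
  expect_true(pr2$protein_contaminated)
  expect_true(any(abs(pr2$protein_bands - 1004) <= 5))
})

test_that("sub-threshold protein stays below the 5-sigma screen", {
  # protein weight tuned so the phenylalanine amplitude is 2 * noise_sd
  noise <- 0.5
  u <- band_model(532)$area_unit
  w <- 2 * noise * pi * 5 / (2.5 * u)
  s <- subtract_background(
    simulate_cell(cell_profile(protein = w), 75, noise_sd = noise, seed = 2))
  expect_false(protein_screen(s, noise_sd = noise)$protein_contaminated)
})

test_that("screen decisions are invariant to joint intensity/noise rescaling", {
  s <- subtract_background(simulate_cell(cell_profile(protein = 1), 75,
                                         noise_sd = 0.5, seed = 3))
  big <- s
  big$intensity <- s$intensity * 40
  expect_equal(protein_screen(s, noise_sd = 0.5)$protein_contaminated,
               protein_screen(big, noise_sd = 20)$protein_contaminated)
  expect_equal(photobleach_check(s, noise_sd = 0.5)$photobleach_ok,
               photobleach_check(big, noise_sd = 20)$photobleach_ok)
})

test_that("photobleach check fails before bleaching and passes after", {
  pre <- subtract_background(simulate_cell(cell_profile(), 0, noise_sd = 0.5, seed = 4))
  post <- subtract_background(simulate_cell(cell_profile(), 75, noise_sd = 0.5, seed = 4))
  expect_false(photobleach_check(pre)$photobleach_ok)
  chk <- photobleach_check(post)
  expect_true(chk$photobleach_ok)
  expect_lt(chk$carotenoid_to_lipid, 0.5)
})

test_that("carotenoid-free spectra pass trivially with ratio zero", {
  s <- subtract_background(simulate_standard(oleic(), 532, noise_sd = 0.5, seed = 5))
  chk <- photobleach_check(s)
  expect_true(chk$photobleach_ok)
  expect_equal(chk$carotenoid_to_lipid, 0)
})

test_that("a spectrum without a 1440 band fails the check with a reason", {
  wn <- default_wavenumbers()
  s <- make_spec(lorentzian(wn, 1520, 50, 6))
  chk <- photobleach_check(s, noise_sd = 0.5)
  expect_false(chk$photobleach_ok)
  expect_match(chk$reason, "1440")
})

test_that("qc_spectrum aggregates both checks", {
  cell <- subtract_background(simulate_cell(cell_profile(), 75, noise_sd = 0.5, seed = 6))
  rep <- qc_spectrum(cell, noise_sd = 0.5)
  expect_true(rep$pass)
  expect_gt(rep$snr, 50)
  bad <- subtract_background(simulate_cell(cell_profile(), 0, noise_sd = 0.5, seed = 6))
  expect_false(qc_spectrum(bad, noise_sd = 0.5)$pass)
})
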