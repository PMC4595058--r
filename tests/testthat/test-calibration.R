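test_that("exact linear data is fitted exactly", {
  m <- fit_linear(c(0, 1, 2, 3), c(0, 2, 4, 6))
  expect_equal(unname(m$params["slope"]), 2)
  expect_equal(unname(m$params["intercept"]), 0, tolerance = 1e-12)
  expect_equal(m$r_squared, 1)
  expect_error(fit_linear(c(1, 1, 1), c(1, 2, 3)), "degenerate")
})

test_that("the isolate panel reproduces its own printed estimates", {
  tab <- reference_isolates()
  m <- fit_linear(tab$ratio, tab$c_double_bonds)
  expect_equal(unname(m$params["slope"]), 1.64, tolerance = 0.005)
  expect_equal(unname(m$params["intercept"]), -0.045, tolerance = 0.02)
  expect_equal(round(predict_calibration(m, 0.57), 2), 0.89)
})

test_that("linear predict/invert round trip is exact", {
  m <- fit_linear(c(0.1, 0.5, 0.9, 1.3), c(0.2, 0.85, 1.4, 2.1))
  for (x in c(0, 0.3, 0.77, 2)) {
    expect_equal(invert_calibration(m, predict_calibration(m, x)), x,
                 tolerance = 1e-9)
  }
})

test_that("sigmoid calibration is decreasing, accurate and range-guarded", {
  reg <- standard_registry()
  mp <- vapply(reg, `[[`, 0, "melting_point")
  ratio <- vapply(reg, function(fa) 7.3 * fa$n_double_bonds / fa$n_ch2, 0)
  m <- fit_sigmoid_mp(mp, ratio)
  expect_gt(m$r_squared, 0.8)
  grid <- seq(-60, 70, length.out = 200)
  pred <- predict_calibration(m, grid)
  expect_true(all(diff(pred) < 0))
  # asymptote values have no finite preimage
  expect_error(invert_calibration(m, m$params[["upper"]]), "range")
  expect_error(invert_calibration(m, m$params[["lower"]] - 0.1), "range")
  # oleic-like ratio inverts near the oleic melting point
  expect_gt(invert_calibration(m, 0.52), 8)
  expect_lt(invert_calibration(m, 0.52), 14)
})

test_that("sigmoid fit needs enough points and spread", {
  expect_error(fit_sigmoid_mp(c(1, 2, 3), c(3, 2, 1)), "at least 5")
  expect_error(fit_sigmoid_mp(1:5, rep(1, 5)), "degenerate")
})

test_that("mixture ratios interpolate monotonically between pure components", {
  r_oleic <- mixture_ratio(c("C18:1" = 1))
  r_palmitoleic <- mixture_ratio(c("C16:1" = 1))
  expect_equal(r_oleic, 7.3 / 14)
  expect_equal(r_palmitoleic, 7.3 / 12)
  half <- mixture_ratio(c("C18:1" = 0.5, "C16:1" = 0.5))
  expect_gt(half, r_oleic)
  expect_lt(half, r_palmitoleic)
  # closed-form check of the mole-weighted 50/50 value
  mo <- 0.5 / 282.468; mp_ <- 0.5 / 254.414
  expect_equal(half, 7.3 * (mo + mp_) / (mo * 14 + mp_ * 12), tolerance = 1e-9)
  sweep <- vapply(seq(0, 1, by = 0.1), function(w)
    mixture_ratio(c("C18:1" = 1 - w, "C16:1" = w)), 0)
  expect_true(all(diff(sweep) > 0))
  expect_error(mixture_ratio(c("C18:1" = 0.6, "C16:1" = 0.6)), "sum to 1")
})

test_that("quantify applies and inverts all three models with QC guards", {
  mods <- c(isolate_calibration(532), list(mp = NULL))
  cs <- subtract_background(simulate_cell(cell_profile(), 75, 532, seed = 21))
  q <- quantify(cs, mods, noise_sd = 0.5)
  expect_lt(abs(q$r1650_1440 - 0.52), 0.05)
  expect_lt(abs(q$est_c_double_bonds - 0.80), 0.05)
  expect_lt(abs(q$est_n_ratio - 0.07), 0.01)
  expect_true(is.na(q$est_melting_point))
  # excitation mismatch is refused
  cs785 <- subtract_background(simulate_cell(cell_profile(), 75, 785, seed = 21))
  expect_error(quantify(cs785, mods, noise_sd = 0.5), "785")
})

test_that("negative property estimates are clipped to zero with a warning", {
  mods <- isolate_calibration(532)
  s <- subtract_background(simulate_standard(registry_fa("C16:0"), 532,
                                             noise_sd = 0.5, seed = 22))
  w <- capture_warnings(q <- quantify(s, mods, noise_sd = 0.5))
  expect_match(w, "clipped", all = FALSE)
  expect_identical(q$est_c_double_bonds, 0)
})

test_that("calibration models survive text serialization", {
  pan <- calibrate_panel(excitation_nm = 532, noise_sd = 0.5, seed = 31)
  for (nm in c("c_bonds", "n_ratio", "mp")) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_calibration(pan[[nm]], path)
    m2 <- read_calibration(path)
    expect_equal(m2$params, pan[[nm]]$params, tolerance = 1e-9, info = nm)
    expect_equal(m2$kind, pan[[nm]]$kind)
    expect_equal(m2$excitation_nm, 532)
  }
})

test_that("population classification separates the three archetypes", {
  set.seed(33)
  wild <- rnorm(30, 0.80, 0.05)
  res <- classify_population(wild)
  expect_equal(unname(res$counts[["monounsaturated-dominant"]]), 30)
  expect_equal(res$n_occupied, 1)

  mutant <- c(rnorm(10, 0.1, 0.05), rnorm(10, 0.5, 0.05), rnorm(10, 0.9, 0.05))
  res3 <- classify_population(mutant)
  expect_equal(res3$n_occupied, 3)
  expect_equal(sum(res3$counts), 30)

  same <- classify_population(rep(0.5, 12))
  expect_equal(same$n_occupied, 1)
  expect_equal(sum(same$counts), 12)
})
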