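# 1.5 um droplet radius: a mature algal lipid body, comparable to the
# 2 um pixel pitch of the coarse 10 x 10 survey scan so it cannot fall
# unseen between sampling points
droplet_scene <- function(center = c(7, 3), noise_sd = 0.5, ...) {
  raman_scene(extent = c(20, 20),
              droplets = list(scene_droplet(center, 1.5)),
              uniform = c(chlorophyll = 0.1), fluorescence = 2,
              noise_sd = noise_sd, ...)
}

test_that("optics closed forms reproduce the instrument's printed values", {
  # compared at the three decimals the instrument specification prints
  expect_equal(round(spot_size(532, 0.8), 3), 0.811)
  expect_equal(round(spot_size(785, 0.8), 3), 1.197)
  expect_equal(round(lateral_resolution(532, 0.8), 3), 0.279)
  expect_equal(round(lateral_resolution(785, 0.8), 3), 0.412)
  expect_equal(spot_size(800, 0.976), 1.000, tolerance = 0.001)
  expect_equal(lateral_resolution(532, 0.8) / lateral_resolution(532, 0.4), 0.5)
  expect_error(spot_size(-5, 0.8), "positive")
  expect_error(spot_size(532, 1.7), "aperture")
})

test_that("uniform scenes give flat band images", {
  sc <- raman_scene(extent = c(10, 10), uniform = c(lipid = 0.5),
                    noise_sd = 0)
  h <- sample_hypercube(sc, c(5, 5), 6, n = 4, seed = 1)
  img <- band_image(h)
  expect_lt(diff(range(img$values)) / max(img$values), 1e-6)
})

test_that("a planted droplet lights up the right pixel", {
  sc <- droplet_scene(center = c(10.5, 10.5), noise_sd = 0)
  h <- sample_hypercube(sc, c(10, 10), 10, n = 10, seed = 2)
  img <- band_image(h)
  best <- image_argmax(img$values)
  expect_equal(pixel_center(h, best["ix"], best["iy"]), c(10.5, 10.5),
               tolerance = 0.5, ignore_attr = TRUE)
})

test_that("halving the window quadruples the droplet's pixel footprint", {
  sc <- droplet_scene(center = c(10, 10), noise_sd = 0)
  count_bright <- function(window) {
    h <- sample_hypercube(sc, c(10, 10), window, n = 16, seed = 3)
    v <- band_image(h)$values
    sum(v > max(v) / 2)
  }
  n_w <- count_bright(12)
  n_half <- count_bright(6)
  expect_gt(n_half / n_w, 2.5)
  expect_lt(n_half / n_w, 6)
})

test_that("band image totals scale linearly with lipid concentration", {
  img_total <- function(amount) {
    sc <- raman_scene(extent = c(10, 10),
                      droplets = list(scene_droplet(c(5, 5), 1,
                                                    intensity = amount)),
                      noise_sd = 0)
    h <- sample_hypercube(sc, c(5, 5), 4, n = 6, seed = 4)
    sum(band_image(h)$values)
  }
  t1 <- img_total(1)
  t3 <- img_total(3)
  expect_equal(t3 / t1, 3, tolerance = 1e-6)
})

test_that("component maps separate disjoint protein/carotenoid/lipid patches", {
  sc <- raman_scene(extent = c(12, 12),
                    droplets = list(scene_droplet(c(2.5, 2.5), 1)),
                    patches = list(
                      scene_patch(c(9.5, 2.5), 1, "carotenoid", 0.3),
                      scene_patch(c(6, 9.5), 1, "protein", 0.5)),
                    noise_sd = 0)
  h <- sample_hypercube(sc, c(6, 6), 12, n = 8, seed = 5)
  maps <- component_maps(h)
  lip_best <- image_argmax(maps$lipid$values)
  car_best <- image_argmax(maps$carotenoid$values)
  expect_false(all(lip_best == car_best))
  # composite recovers each patch's label at its own location
  expect_equal(maps$composite[2, 2], "lipid")
  expect_equal(maps$composite[7, 2], "carotenoid")
  expect_equal(maps$composite[4, 7], "protein")
  # and is invariant to global rescaling
  h2 <- h
  h2$intensity <- h$intensity * 11
  expect_identical(component_maps(h2)$composite, maps$composite)
})

test_that("coarse-to-fine localization lands on the planted droplet", {
  sc <- droplet_scene(center = c(7, 3))
  loc <- suppressWarnings(
    locate_lipid_region(sc, c(10, 10), 20, excitation_nm = 532, seed = 6))
  expect_lt(sqrt(sum((loc$center - c(7, 3))^2)), 0.5)
  expect_equal(loc$iterations, ceiling(log2(20 / 1)))
  expect_equal(nrow(loc$trace), loc$iterations)
  expect_s3_class(loc$spectrum, "raman_spectrum")
})

test_that("localization converges monotonically and ignores the start point", {
  sc <- droplet_scene(center = c(13, 6), noise_sd = 0)
  loc <- suppressWarnings(
    locate_lipid_region(sc, c(10, 10), 16, excitation_nm = 532))
  d <- sqrt((loc$trace$x - 13)^2 + (loc$trace$y - 6)^2)
  expect_true(all(diff(d) <= 1e-9))
  loc2 <- suppressWarnings(
    locate_lipid_region(sc, c(8, 11), 16, excitation_nm = 532))
  expect_equal(loc2$center, loc$center, tolerance = 0.3)
})

test_that("the brighter of two droplets wins", {
  sc <- raman_scene(extent = c(20, 20),
                    droplets = list(scene_droplet(c(5, 5), 1.5, intensity = 1),
                                    scene_droplet(c(15, 14), 1.5, intensity = 2)),
                    noise_sd = 0)
  loc <- suppressWarnings(locate_lipid_region(sc, c(10, 10), 20, seed = 7))
  expect_lt(sqrt(sum((loc$center - c(15, 14))^2)), 0.5)
})

test_that("featureless scenes make localization fail", {
  flat <- raman_scene(extent = c(20, 20), uniform = c(lipid = 0.3),
                      noise_sd = 0)
  expect_error(suppressWarnings(
    locate_lipid_region(flat, c(10, 10), 20, seed = 8)), "noise floor")
})

test_that("NIR localization uses the CH2-bend band and still succeeds", {
  sc <- droplet_scene(center = c(12, 8))
  expect_equal(default_lipid_band(785), c(1380, 1500))
  expect_equal(default_lipid_band(532), c(2800, 3000))
  loc <- suppressWarnings(
    locate_lipid_region(sc, c(10, 10), 20, excitation_nm = 785, seed = 9))
  expect_lt(sqrt(sum((loc$center - c(12, 8))^2)), 0.5)
})
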