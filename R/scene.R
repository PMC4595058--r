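#' Synthetic microscopy scene
#'
#' A continuous 2D description of a sample region: circular lipid droplets
#' and pigment/protein patches on an optionally uniform background, plus a
#' fluorescence level. Scenes are resolution-free; [sample_hypercube()]
#' renders them through the diffraction-limited point-spread function at
#' any pixel density, so the same scene can be re-scanned at finer
#' windows. Coordinates are in micrometres, origin at the lower-left
#' corner, x right and y up.
#'
#' @param extent `c(width, height)` of the scene in um.
#' @param droplets list of [scene_droplet()] objects.
#' @param patches list of [scene_patch()] objects.
#' @param uniform named numeric vector of uniform background weights
#'   (`lipid`, `carotenoid`, `chlorophyll`, `protein`), all >= 0.
#' @param uniform_lipids lipid mixture of the uniform background.
#' @param fluorescence uniform fluorescence weight.
#' @param noise_sd detector noise (counts) used when sampling.
#' @return object of class `raman_scene`.
#' @export
raman_scene <- function(extent = c(20, 20), droplets = list(),
                        patches = list(),
                        uniform = c(lipid = 0, carotenoid = 0,
                                    chlorophyll = 0, protein = 0),
                        uniform_lipids = c("C18:1" = 1),
                        fluorescence = 0, noise_sd = 0.5) {
  defaults <- c(lipid = 0, carotenoid = 0, chlorophyll = 0, protein = 0)
  defaults[names(uniform)] <- uniform
  if (any(defaults < 0) || fluorescence < 0)
    stop("scene background weights must be >= 0")
  for (d in droplets) {
    if (any(d$center < 0) || d$center[1] > extent[1] || d$center[2] > extent[2])
      stop("droplet center outside scene extent")
  }
  structure(list(extent = extent, droplets = droplets, patches = patches,
                 uniform = defaults,
                 uniform_counts = mixture_counts(uniform_lipids),
                 fluorescence = fluorescence, noise_sd = noise_sd),
            class = "raman_scene")
}

#' Scene building blocks
#'
#' `scene_droplet()` plants a spherical lipid body of a given fatty-acid
#' mixture: its projected signal is the chord-length profile
#' `sqrt(1 - (d/radius)^2)` (normalized to the droplet center), peaked at
#' the center as a confocal scan of a sphere is. `scene_patch()` plants a
#' flat circular region of carotenoid, chlorophyll or protein signal.
#'
#' @param center `c(x, y)` in um.
#' @param radius radius in um, > 0.
#' @param lipids named weight-fraction vector of the droplet's lipid
#'   mixture.
#' @param intensity amount scale of the object (dimensionless).
#' @return a list describing the object.
#' @export
scene_droplet <- function(center, radius, lipids = c("C18:1" = 1),
                          intensity = 1) {
  stopifnot(radius > 0, intensity >= 0, length(center) == 2)
  list(center = center, radius = radius, lipids = lipids,
       counts = mixture_counts(lipids), intensity = intensity)
}

#' @param component one of `"carotenoid"`, `"chlorophyll"`, `"protein"`.
#' @rdname scene_droplet
#' @export
scene_patch <- function(center, radius,
                        component = c("carotenoid", "chlorophyll", "protein"),
                        intensity = 1) {
  component <- match.arg(component)
  stopifnot(radius > 0, intensity >= 0, length(center) == 2)
  list(center = center, radius = radius, component = component,
       intensity = intensity)
}

# fraction of an isotropic Gaussian PSF (sd sigma) centered at distance d
# that falls inside a disk of radius R: noncentral chi-square CDF.
psf_disk_overlap <- function(d, R, sigma) {
  stats::pchisq((R / sigma)^2, df = 2, ncp = (d / sigma)^2)
}

# component weights seen by a PSF centered at point p = c(x, y);
# points outside the scene extent see empty substrate
scene_weights_at <- function(scene, p, sigma) {
  if (p[1] < 0 || p[2] < 0 || p[1] > scene$extent[1] || p[2] > scene$extent[2])
    return(c(n_ch2 = 0, n_double_bonds = 0, carotenoid = 0,
             chlorophyll = 0, protein = 0, fluorescence = 0))
  w <- c(n_ch2 = scene$uniform[["lipid"]] * scene$uniform_counts$n_ch2,
         n_double_bonds = scene$uniform[["lipid"]] *
           scene$uniform_counts$n_double_bonds,
         carotenoid = scene$uniform[["carotenoid"]],
         chlorophyll = scene$uniform[["chlorophyll"]],
         protein = scene$uniform[["protein"]],
         fluorescence = scene$fluorescence)
  for (d in scene$droplets) {
    dist <- sqrt(sum((p - d$center)^2))
    # spherical-body projection, smoothed at the rim by the PSF overlap
    amt <- d$intensity * psf_disk_overlap(dist, d$radius, sigma) *
      sqrt(max(0, 1 - (dist / d$radius)^2))
    w[["n_ch2"]] <- w[["n_ch2"]] + amt * d$counts$n_ch2
    w[["n_double_bonds"]] <- w[["n_double_bonds"]] + amt * d$counts$n_double_bonds
  }
  for (pa in scene$patches) {
    dist <- sqrt(sum((p - pa$center)^2))
    amt <- pa$intensity * psf_disk_overlap(dist, pa$radius, sigma)
    w[[pa$component]] <- w[[pa$component]] + amt
  }
  w
}

#' Sample a hyperspectral map from a scene
#'
#' Renders an `n x n` grid of spectra over a square window of the scene.
#' Each pixel integrates the scene over a Gaussian spot whose FWHM is the
#' diffraction-limited lateral resolution of the chosen excitation
#' ([lateral_resolution()], NA 0.8). Pixel centers tile the half-open
#' window `[cx - w/2, cx + w/2) x [cy - w/2, cy + w/2)`; re-sampling the
#' same scene at a finer window around a feature reveals it at
#' proportionally higher pixel density.
#'
#' @param scene a [raman_scene()].
#' @param center `c(x, y)` window center in um.
#' @param window window side length in um, > 0.
#' @param n pixels per side (>= 2); the default 10 x 10 matches a fast
#'   coarse survey scan.
#' @param excitation_nm 532 or 785.
#' @param seed seed for the per-pixel noise.
#' @param numerical_aperture collection objective NA.
#' @param wavenumber spectral grid.
#' @param bm generator constants.
#' @return a [hypercube()].
#' @export
sample_hypercube <- function(scene, center, window, n = 10,
                             excitation_nm = 532, seed = NULL,
                             numerical_aperture = 0.8,
                             wavenumber = default_wavenumbers(),
                             bm = band_model(excitation_nm)) {
  stopifnot(inherits(scene, "raman_scene"), window > 0, n >= 2)
  step <- window / n
  px <- center[1] - window / 2 + (seq_len(n) - 0.5) * step
  py <- center[2] - window / 2 + (seq_len(n) - 0.5) * step
  if (min(px) < 0 || max(px) > scene$extent[1] ||
      min(py) < 0 || max(py) > scene$extent[2])
    warning("sampling window extends beyond the scene extent; outside area is empty",
            call. = FALSE)
  sigma <- lateral_resolution(excitation_nm, numerical_aperture) / 2.3548

  basis <- band_basis(wavenumber, bm)
  W <- matrix(0, n * n, ncol(basis))
  colnames(W) <- colnames(basis)
  for (iy in seq_len(n)) {
    for (ix in seq_len(n)) {
      W[(iy - 1) * n + ix, ] <-
        scene_weights_at(scene, c(px[ix], py[iy]), sigma)
    }
  }
  intens <- W %*% t(basis)   # (n*n) x n_wavenumber
  if (scene$noise_sd > 0) {
    intens <- intens + with_seed(seed,
      matrix(stats::rnorm(length(intens), 0, scene$noise_sd), nrow(intens)))
  }
  hypercube(intensity = intens, nx = n, ny = n, step = step,
            origin = c(center[1] - window / 2, center[2] - window / 2),
            wavenumber = wavenumber, excitation_nm = excitation_nm)
}

# single spectrum at an arbitrary scene point (used for best-spectrum
# extraction after localization)
scene_spectrum_at <- function(scene, p, excitation_nm = 532, seed = NULL,
                              numerical_aperture = 0.8,
                              wavenumber = default_wavenumbers(),
                              bm = band_model(excitation_nm)) {
  sigma <- lateral_resolution(excitation_nm, numerical_aperture) / 2.3548
  w <- scene_weights_at(scene, p, sigma)
  with_seed(seed, compose_spectrum(
    wavenumber, w, bm, scene$noise_sd,
    meta = list(x_um = p[1], y_um = p[2], excitation_nm = excitation_nm)))
}
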