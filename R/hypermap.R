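#' Hyperspectral cube
#'
#' A 2D grid of Raman spectra sharing one wavenumber axis, covering a
#' physical scan window. Pixel (1, 1) sits at the lower-left; x is the
#' fast index.
#'
#' @param intensity numeric matrix, `nx * ny` rows (pixels, x fastest) by
#'   `length(wavenumber)` columns.
#' @param nx,ny pixel counts (`nx * ny >= 4`).
#' @param step um per pixel.
#' @param origin `c(x, y)` of the window's lower-left corner in um.
#' @param wavenumber shared spectral axis.
#' @param excitation_nm 532 or 785.
#' @return object of class `hypercube`.
#' @export
hypercube <- function(intensity, nx, ny, step, origin, wavenumber,
                      excitation_nm) {
  if (nx * ny < 4) stop("hypercube needs at least 4 pixels")
  if (nrow(intensity) != nx * ny || ncol(intensity) != length(wavenumber))
    abort_format("hypercube intensity matrix shape does not match nx, ny and the grid")
  structure(list(intensity = intensity, nx = nx, ny = ny, step = step,
                 origin = origin, wavenumber = as.numeric(wavenumber),
                 excitation_nm = excitation_nm),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  cat(sprintf("<hypercube> %d x %d pixels (%.3g um/px), %d-point spectra, %g nm\n",
              x$nx, x$ny, x$step, length(x$wavenumber), x$excitation_nm))
  invisible(x)
}

#' Extract one pixel of a hypercube as a spectrum
#'
#' @param h a [hypercube()].
#' @param ix,iy pixel indices (1-based, from the lower-left).
#' @return a [raman_spectrum()].
#' @export
pixel_spectrum <- function(h, ix, iy) {
  stopifnot(ix >= 1, ix <= h$nx, iy >= 1, iy <= h$ny)
  raman_spectrum(h$wavenumber, h$intensity[(iy - 1) * h$nx + ix, ],
                 h$excitation_nm,
                 meta = list(ix = ix, iy = iy))
}

# physical center coordinates of pixel (ix, iy)
pixel_center <- function(h, ix, iy) {
  c(h$origin[1] + (ix - 0.5) * h$step, h$origin[2] + (iy - 0.5) * h$step)
}

# default lipid marker band: the most intense lipid feature under each
# laser (CH stretches in the green, CH2 bend in the NIR)
default_lipid_band <- function(excitation_nm) {
  if (excitation_nm == 532) c(2800, 3000) else c(1380, 1500)
}

#' Band-integral chemical image
#'
#' Per-pixel integrated intensity over a wavenumber band, after
#' moving-average background subtraction of each pixel spectrum. The
#' default band is the excitation-appropriate lipid marker
#' (2800-3000 cm^-1 at 532 nm, 1380-1500 cm^-1 at 785 nm).
#'
#' @param h a [hypercube()].
#' @param band wavenumber interval `c(lo, hi)` inside the grid.
#' @param label image label.
#' @param subtract apply [subtract_background()] per pixel (default TRUE).
#' @param background_window_cm1 moving-average window.
#' @return object of class `band_image`: list with `values` (nx x ny
#'   matrix, counts cm^-1), `band`, `label`, `step`, `origin`.
#' @export
band_image <- function(h, band = NULL, label = "lipid", subtract = TRUE,
                       background_window_cm1 = 600) {
  stopifnot(inherits(h, "hypercube"))
  band <- band %||% default_lipid_band(h$excitation_nm)
  if (band[1] < min(h$wavenumber) || band[2] > max(h$wavenumber))
    stop(sprintf("band [%g, %g] outside the spectral grid", band[1], band[2]))
  vals <- matrix(NA_real_, h$nx, h$ny)
  for (iy in seq_len(h$ny)) {
    for (ix in seq_len(h$nx)) {
      s <- pixel_spectrum(h, ix, iy)
      if (subtract) s <- subtract_background(s, background_window_cm1)
      vals[ix, iy] <- band_integral(s, band)
    }
  }
  structure(list(values = vals, band = band, label = label,
                 step = h$step, origin = h$origin),
            class = "band_image")
}

#' @export
print.band_image <- function(x, ...) {
  cat(sprintf("<band_image> '%s' [%g, %g] cm^-1, %d x %d px, max %.4g\n",
              x$label, x$band[1], x$band[2], nrow(x$values), ncol(x$values),
              max(x$values)))
  invisible(x)
}

# argmax pixel with the documented deterministic tie-break:
# lowest (row = y, column = x) index, i.e. lowest iy, then lowest ix
image_argmax <- function(values) {
  m <- max(values)
  hits <- which(t(values) == m, arr.ind = TRUE)  # t(): rows = iy
  c(ix = unname(hits[1, 2]), iy = unname(hits[1, 1]))
}

#' Component chemical maps and composite label image
#'
#' Band-integral images of the three major cellular components - protein
#' (995-1012 cm^-1, phenylalanine), carotenoid (1505-1535 cm^-1) and
#' lipid (1380-1500 cm^-1, CH2 bend) - plus a composite image assigning
#' each pixel the label of its largest max-normalized component. Pixels
#' where every component stays below `floor_fraction` of the global
#' normalized maximum are labelled `"background"`; the labeling is
#' invariant to rescaling all intensities by a common factor.
#'
#' @param h a [hypercube()].
#' @param floor_fraction background floor as a fraction of the strongest
#'   normalized component (default 0.1).
#' @return list with `protein`, `carotenoid`, `lipid` ([band_image()]s)
#'   and `composite` (nx x ny character matrix of labels).
#' @export
component_maps <- function(h, floor_fraction = 0.1) {
  imgs <- list(
    protein = band_image(h, c(995, 1012), "protein"),
    carotenoid = band_image(h, c(1505, 1535), "carotenoid"),
    lipid = band_image(h, c(1380, 1500), "lipid")
  )
  norm <- lapply(imgs, function(im) {
    m <- max(im$values)
    if (m > 0) im$values / m else im$values * 0
  })
  labels <- names(imgs)
  comp <- matrix("background", h$nx, h$ny)
  for (iy in seq_len(h$ny)) {
    for (ix in seq_len(h$nx)) {
      v <- vapply(norm, `[`, 0, ix, iy)
      if (max(v) > floor_fraction) comp[ix, iy] <- labels[which.max(v)]
    }
  }
  c(imgs, list(composite = comp))
}

#' Coarse-to-fine lipid-body localization
#'
#' The guided-scan loop of the acquisition workflow: scan an `n x n`
#' hypercube over the current window, form the lipid band-integral image,
#' re-center on its maximum pixel, halve the window, and repeat until the
#' window is at most `stop_window` (about 1 x 1 um^2); the iteration count
#' is therefore `ceiling(log2(start_window / stop_window))`. Returns the
#' final center and the single best spectrum extracted there. Ties at the
#' image maximum break deterministically to the lowest (row, column)
#' index. If the first image shows no pixel above the noise floor the
#' localization fails.
#'
#' @param scene a [raman_scene()].
#' @param start_center,start_window initial window center (um) and side
#'   length (um).
#' @param n pixels per side of every scan (default 10).
#' @param excitation_nm 532 or 785; also selects the lipid marker band.
#' @param stop_window final window size (um), default 1.
#' @param seed seed; each iteration's scan noise derives from it.
#' @param band lipid band override.
#' @return list with `center` (um), `spectrum` (the extracted
#'   [raman_spectrum()]), `iterations`, and `trace` (data frame of
#'   iteration, center and window).
#' @export
locate_lipid_region <- function(scene, start_center, start_window, n = 10,
                                excitation_nm = 532, stop_window = 1,
                                seed = NULL, band = NULL) {
  stopifnot(start_window > stop_window, n >= 2)
  band <- band %||% default_lipid_band(excitation_nm)
  center <- start_center
  window <- start_window
  trace <- list()
  iter <- 0
  while (window > stop_window) {
    iter <- iter + 1
    h <- sample_hypercube(scene, center, window, n, excitation_nm,
                          seed = if (is.null(seed)) NULL else seed + iter)
    img <- band_image(h, band)
    v <- as.numeric(img$values)
    if (iter == 1 && (max(v) - stats::median(v)) <= 5 * stats::mad(v) + 1e-12)
      stop("localization failed: no pixel rises above the noise floor")
    best <- image_argmax(img$values)
    center <- pixel_center(h, best["ix"], best["iy"])
    trace[[iter]] <- data.frame(iteration = iter, x = center[1],
                                y = center[2], window = window)
    window <- window / 2
  }
  spec <- scene_spectrum_at(scene, center, excitation_nm,
                            seed = if (is.null(seed)) NULL else seed)
  list(center = unname(center), spectrum = spec, iterations = iter,
       trace = do.call(rbind, trace))
}

#' Diffraction-limited optics helpers
#'
#' `spot_size()` is the Airy-disk diameter `1.22 * lambda / NA`;
#' `lateral_resolution()` is the theoretical diffraction-limited lateral
#' resolution `0.42 * lambda / NA`. Both in micrometres.
#'
#' @param excitation_nm excitation wavelength in nm, > 0.
#' @param numerical_aperture objective NA, in (0, 1.5].
#' @return micrometres.
#' @examples
#' spot_size(532, 0.8)           # 0.811 um
#' lateral_resolution(785, 0.8)  # 0.412 um
#' @export
spot_size <- function(excitation_nm, numerical_aperture) {
  check_optics(excitation_nm, numerical_aperture)
  1.22 * (excitation_nm / 1000) / numerical_aperture
}

#' @rdname spot_size
#' @export
lateral_resolution <- function(excitation_nm, numerical_aperture) {
  check_optics(excitation_nm, numerical_aperture)
  0.42 * (excitation_nm / 1000) / numerical_aperture
}

check_optics <- function(excitation_nm, numerical_aperture) {
  if (excitation_nm <= 0) stop("excitation wavelength must be positive")
  if (numerical_aperture <= 0 || numerical_aperture > 1.5)
    stop("numerical aperture must be in (0, 1.5]")
  invisible(TRUE)
}
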