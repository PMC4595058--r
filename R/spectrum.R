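#' Construct a Raman spectrum
#'
#' The atomic unit of the pipeline: a strictly increasing, uniform
#' wavenumber grid (default 0-3399 cm^-1 at 3 cm^-1 steps, matching a
#' 600 g/mm spectrograph), detector counts, the excitation wavelength and
#' free-form key-value metadata.
#'
#' @param wavenumber numeric vector, strictly increasing, uniform step.
#' @param intensity numeric vector of detector counts, same length.
#' @param excitation_nm excitation wavelength, 532 or 785.
#' @param meta named list of metadata strings.
#' @return object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(wavenumber, intensity, excitation_nm,
                           meta = list()) {
  if (length(wavenumber) != length(intensity))
    abort_format("wavenumber and intensity lengths differ")
  if (length(wavenumber) < 4) abort_format("spectrum too short")
  d <- diff(wavenumber)
  if (any(d <= 0)) abort_format("wavenumber axis must be strictly increasing")
  if (max(d) - min(d) > 1e-9)
    abort_format("wavenumber grid must be uniform")
  if (!excitation_nm %in% c(532, 785))
    stop("unsupported excitation wavelength: ", excitation_nm, " nm")
  if (any(!is.finite(intensity))) abort_format("intensities must be finite")
  structure(list(wavenumber = as.numeric(wavenumber),
                 intensity = as.numeric(intensity),
                 excitation_nm = excitation_nm,
                 meta = meta),
            class = "raman_spectrum")
}

#' Default wavenumber grid
#'
#' @param min,max,step grid limits and spacing in cm^-1.
#' @return numeric vector `seq(min, max, by = step)`.
#' @export
default_wavenumbers <- function(min = 0, max = 3399, step = 3) {
  seq(min, max, by = step)
}

grid_step <- function(s) s$wavenumber[2] - s$wavenumber[1]

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d points, %.0f-%.0f cm^-1 (step %.3g), %g nm excitation\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber),
              grid_step(x), x$excitation_nm))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# window helpers -------------------------------------------------------------

window_index <- function(s, window) {
  if (window[1] >= window[2]) stop("empty spectral window")
  i <- which(s$wavenumber >= window[1] & s$wavenumber <= window[2])
  if (length(i) < 4)
    stop(sprintf("window [%g, %g] cm^-1 is outside (or too small for) the spectral grid",
                 window[1], window[2]))
  i
}

# trapezoidal integral of the spectrum over a window (counts * cm^-1)
band_integral <- function(s, window) {
  i <- window_index(s, window)
  pracma::trapz(s$wavenumber[i], s$intensity[i])
}
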