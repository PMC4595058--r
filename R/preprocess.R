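#' Moving-average background subtraction
#'
#' Subtracts a centered moving average of the spectrum from itself,
#' removing broad fluorescence and instrument background while leaving
#' narrow Raman bands (with a constant, window-dependent distortion that a
#' peak fit's offset term absorbs). Edges are reflect-padded. The same
#' window must, by contract, be applied to calibration standards and
#' unknowns alike. The default 600 cm^-1 (about 200 grid points) is wide
#' compared to condensed-phase Raman bands and narrow compared to the
#' fluorescence baseline; critically, it is wide enough that each strong
#' band's contribution to the average is *constant* across the
#' neighboring analysis windows, so the distortion it leaves is a flat
#' pedestal a fit's offset absorbs rather than a composition-dependent
#' ramp.
#'
#' The operation is linear in the spectrum; a constant spectrum maps to
#' exactly zero.
#'
#' @param s a [raman_spectrum()].
#' @param window_cm1 moving-average window width in cm^-1 (>= 3 grid steps).
#' @return the background-subtracted [raman_spectrum()].
#' @export
subtract_background <- function(s, window_cm1 = 600) {
  stopifnot(inherits(s, "raman_spectrum"))
  step <- grid_step(s)
  if (window_cm1 < 3 * step)
    stop("background window must be at least 3 grid steps (", 3 * step, " cm^-1)")
  span <- diff(range(s$wavenumber))
  if (window_cm1 > span)
    stop(sprintf("background window (%g cm^-1) exceeds the spectral range (%g cm^-1)",
                 window_cm1, span))
  k <- round(window_cm1 / step)
  if (k %% 2 == 0) k <- k + 1
  y <- s$intensity
  n <- length(y)
  h <- k %/% 2
  padded <- c(rev(y[2:(h + 1)]), y, rev(y[(n - h):(n - 1)]))
  ma <- as.numeric(stats::filter(padded, rep(1 / k, k), sides = 2))
  ma <- ma[(h + 1):(h + n)]
  out <- s
  out$intensity <- y - ma
  out$meta$background_window_cm1 <- window_cm1
  out
}

#' Estimate the detector-noise level of a spectrum
#'
#' Robust noise estimate from first differences in a band-free region
#' (default 1800-2600 cm^-1): `mad(diff(y)) / sqrt(2)`.
#'
#' @param s a [raman_spectrum()].
#' @param quiet_window band-free wavenumber interval.
#' @return estimated noise standard deviation in counts.
#' @export
estimate_noise <- function(s, quiet_window = c(1800, 2600)) {
  i <- window_index(s, quiet_window)
  stats::mad(diff(s$intensity[i])) / sqrt(2)
}

# peak amplitude estimate inside a window: local maximum over the median
window_amplitude <- function(s, window) {
  i <- window_index(s, window)
  y <- s$intensity[i]
  j <- which.max(y)
  list(amplitude = y[j] - stats::median(y), center = s$wavenumber[i][j])
}

# amplitude of the strongest peak *inside* a window: interior local maxima
# only (the rising flank of a band centered outside the window does not
# count), measured against a straight baseline between the window ends so
# that smooth residual background does not register as a peak.
interior_peak_amplitude <- function(s, window) {
  i <- window_index(s, window)
  y <- s$intensity[i]
  x <- s$wavenumber[i]
  n <- length(y)
  e <- min(3, n %/% 2)
  left <- mean(y[seq_len(e)])
  right <- mean(y[seq.int(n - e + 1, n)])
  base <- left + (right - left) * (x - x[1]) / (x[n] - x[1])
  d <- y - base
  interior <- which(c(FALSE, d[2:(n - 1)] > d[1:(n - 2)] &
                        d[2:(n - 1)] >= d[3:n], FALSE))
  if (!length(interior)) return(list(amplitude = 0, center = NA_real_))
  j <- interior[which.max(d[interior])]
  list(amplitude = d[j], center = x[j])
}

#' Protein-contamination screen
#'
#' The C=C-stretch band at 1650 cm^-1 overlaps the protein amide I band,
#' so spectra admitted to ratio analysis must be free of the *other*
#' characteristic protein bands: disulfide near 550 cm^-1, aromatic
#' amino-acid (phenylalanine) near 1004 cm^-1, and amide III at
#' 1220-1300 cm^-1. A window is flagged when it contains a peak whose
#' amplitude exceeds `threshold_sigma` times the noise level.
#'
#' @param s a background-subtracted [raman_spectrum()].
#' @param noise_sd noise standard deviation in counts; estimated with
#'   [estimate_noise()] when `NULL`.
#' @param threshold_sigma detection threshold in units of `noise_sd`
#'   (default 5).
#' @param windows list of screened wavenumber intervals.
#' @return a list with fields `protein_contaminated` (flag),
#'   `protein_bands` (numeric, centers of offending peaks, empty iff not
#'   contaminated), `threshold` (counts) and `noise_sd`.
#' @export
protein_screen <- function(s, noise_sd = NULL, threshold_sigma = 5,
                           windows = list(c(540, 560), c(999, 1009),
                                          c(1220, 1300))) {
  noise_sd <- noise_sd %||% estimate_noise(s)
  threshold <- threshold_sigma * noise_sd
  hits <- numeric(0)
  for (w in windows) {
    # wide windows flanked by lipid bands (amide III sits against the
    # 1300 cm^-1 CH2 twist) only count interior peaks; narrow isolated
    # windows use the plain max-over-median amplitude
    a <- if (diff(w) > 25) interior_peak_amplitude(s, w)
         else window_amplitude(s, w)
    if (!is.na(a$center) && a$amplitude > threshold) hits <- c(hits, a$center)
  }
  list(protein_contaminated = length(hits) > 0,
       protein_bands = hits, threshold = threshold, noise_sd = noise_sd)
}

#' Photobleach adequacy check
#'
#' Controlled photobleaching must push the dominant carotenoid resonance
#' peak (1520 cm^-1) far below the lipid analysis peaks (1440 and
#' 1650 cm^-1). "Far below" is quantified here as integrated area of the
#' 1520 band under `max_ratio` (default 0.5) times the smaller of the
#' detectable lipid-band areas.
#'
#' @inheritParams protein_screen
#' @param max_ratio pass threshold on `area(1520) / min(area(1440),
#'   area(1650))`.
#' @return list with `photobleach_ok` (flag), `carotenoid_to_lipid`
#'   (ratio, >= 0) and `reason` (character, empty when passing).
#' @export
photobleach_check <- function(s, noise_sd = NULL, max_ratio = 0.5) {
  noise_sd <- noise_sd %||% estimate_noise(s)
  a1520 <- band_area_or_zero(s, c(1495, 1545), 1520, noise_sd, hwhm = 6)
  a1440 <- band_area_or_zero(s, c(1380, 1500), 1440, noise_sd)
  a1650 <- band_area_or_zero(s, c(1600, 1700), 1650, noise_sd)
  if (a1440 <= 0)
    return(list(photobleach_ok = FALSE, carotenoid_to_lipid = NA_real_,
                reason = "no detectable 1440 cm^-1 lipid band"))
  if (a1520 <= 0)
    return(list(photobleach_ok = TRUE, carotenoid_to_lipid = 0,
                reason = character(0)))
  lipid <- min(c(a1440, a1650)[c(a1440, a1650) > 0])
  ratio <- a1520 / lipid
  ok <- ratio < max_ratio
  list(photobleach_ok = ok, carotenoid_to_lipid = ratio,
       reason = if (ok) character(0) else
         sprintf("carotenoid 1520 band at %.2f of the lipid bands (limit %g)",
                 ratio, max_ratio))
}

#' Run the full spectral quality control
#'
#' Combines [protein_screen()] and [photobleach_check()] and reports a
#' signal-to-noise figure (1440-band amplitude over noise).
#'
#' @inheritParams protein_screen
#' @return a `qc_report` list: `protein_contaminated`, `protein_bands`,
#'   `photobleach_ok`, `carotenoid_to_lipid`, `snr`, `pass`.
#' @export
qc_spectrum <- function(s, noise_sd = NULL) {
  noise_sd <- noise_sd %||% estimate_noise(s)
  pr <- protein_screen(s, noise_sd)
  pb <- photobleach_check(s, noise_sd)
  amp <- window_amplitude(s, c(1380, 1500))$amplitude
  structure(list(protein_contaminated = pr$protein_contaminated,
                 protein_bands = pr$protein_bands,
                 photobleach_ok = pb$photobleach_ok,
                 carotenoid_to_lipid = pb$carotenoid_to_lipid,
                 reasons = c(if (pr$protein_contaminated)
                   sprintf("protein bands at %s cm^-1",
                           paste(round(pr$protein_bands), collapse = ", ")),
                   pb$reason),
                 snr = if (noise_sd > 0) amp / noise_sd else Inf,
                 pass = !pr$protein_contaminated && pb$photobleach_ok),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>", if (x$pass) "PASS" else "FAIL", "\n")
  cat("  protein contaminated:", x$protein_contaminated,
      if (length(x$protein_bands))
        paste0("(", paste(round(x$protein_bands), collapse = ", "), " cm^-1)") else "", "\n")
  cat("  photobleach ok:", x$photobleach_ok,
      sprintf("(carotenoid/lipid = %.3g)", x$carotenoid_to_lipid), "\n")
  cat(sprintf("  snr: %.3g\n", x$snr))
  invisible(x)
}

#' Optional median-filter despiker
#'
#' Replaces points deviating from a running median by more than
#' `threshold_sigma` noise units with that median. Not applied anywhere by
#' default.
#'
#' @inheritParams protein_screen
#' @param k running-median width (odd integer).
#' @return despiked [raman_spectrum()].
#' @export
despike <- function(s, k = 5, noise_sd = NULL, threshold_sigma = 8) {
  noise_sd <- noise_sd %||% estimate_noise(s)
  med <- stats::runmed(s$intensity, k)
  spike <- abs(s$intensity - med) > threshold_sigma * noise_sd
  out <- s
  out$intensity[spike] <- med[spike]
  out
}
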