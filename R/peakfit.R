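#' Lorentzian multi-peak deconvolution in a band window
#'
#' Nonlinear least squares of a sum of Lorentzian components plus a
#' constant offset, the quantitative core of the ratiometric method.
#' Integrated peak intensities are the *analytic* component areas
#' `pi * amplitude * hwhm`. Fit quality is reported as the explained-area
#' fraction (model area over total positive signal area inside the
#' window); values below 0.999 trigger a quality warning, mirroring the
#' ">= 99.9 % in area" reporting convention of instrument fitting
#' software.
#'
#' @param s a background-subtracted [raman_spectrum()].
#' @param window wavenumber interval `c(lo, hi)` inside the grid.
#' @param n_components number of Lorentzians (>= 1).
#' @param init optional numeric vector of initial center positions
#'   (length `n_components`); defaults to the strongest local maxima.
#' @param init_hwhm initial half width (cm^-1).
#' @param max_restarts random-perturbation restarts on non-convergence.
#' @param seed seed for the restart perturbations (fit is deterministic
#'   given data and initialization).
#' @param baseline local baseline model under the peaks: `"linear"`
#'   (default; absorbs the residual ramp that moving-average background
#'   subtraction leaves near strong neighboring bands) or `"constant"`.
#' @param quality_warning emit the explained-area warning (default TRUE).
#' @return object of class `peak_fit`: list with `peaks` (data frame
#'   `center`, `amplitude`, `hwhm`, `area`, sorted by center), `offset`,
#'   `window`, `explained_area_fraction`, `residual_rms`, `converged`.
#' @examples
#' wn <- default_wavenumbers()
#' s <- raman_spectrum(wn, lorentzian(wn, 1440, 100, 8), 532)
#' fit_window(s, c(1340, 1540), 1)$peaks$area  # ~ pi * 100 * 8
#' @export
fit_window <- function(s, window, n_components = 1, init = NULL,
                       init_hwhm = 8, max_restarts = 5, seed = 0,
                       baseline = c("linear", "constant"),
                       quality_warning = TRUE) {
  stopifnot(inherits(s, "raman_spectrum"), n_components >= 1)
  baseline <- match.arg(baseline)
  i <- window_index(s, window)
  x <- s$wavenumber[i]
  y <- s$intensity[i]
  if (max(y) - min(y) <= .Machine$double.eps * max(1, abs(max(y))))
    abort_fit(sprintf("degenerate window [%g, %g]: no signal variation",
                      window[1], window[2]))
  centers <- init %||% pick_initial_centers(x, y, n_components)
  if (length(centers) != n_components)
    stop("init must supply one center per component")

  off0 <- stats::median(y)
  amp0 <- pmax(vapply(centers, function(cc) y[which.min(abs(x - cc))], 0) - off0,
               max(y) * 1e-3)
  fit <- NULL
  perturb <- with_seed(seed,
    matrix(stats::rnorm(max_restarts * n_components, 0, init_hwhm),
           nrow = max_restarts))
  for (attempt in 0:max_restarts) {
    ctry <- pmin(pmax(centers + if (attempt == 0) 0 else perturb[attempt, ],
                      window[1]), window[2])
    fit <- try_lorentz_nls(x, y, ctry, amp0, init_hwhm, off0, window,
                           linear_baseline = baseline == "linear")
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    abort_fit(sprintf("Lorentzian fit failed to converge in [%g, %g] after %d restarts",
                      window[1], window[2], max_restarts))

  cf <- stats::coef(fit)
  k <- n_components
  peaks <- data.frame(center = cf[paste0("c", seq_len(k))],
                      amplitude = cf[paste0("A", seq_len(k))],
                      hwhm = cf[paste0("g", seq_len(k))])
  peaks$area <- lorentzian_area(peaks$amplitude, peaks$hwhm)
  peaks <- peaks[order(peaks$center), , drop = FALSE]
  rownames(peaks) <- NULL
  off <- cf[["off"]]
  slope <- if (baseline == "linear") cf[["slope"]] else 0
  base <- off + slope * (x - mean(x))

  model_no_off <- rowSums(vapply(seq_len(k), function(j)
    lorentzian(x, peaks$center[j], peaks$amplitude[j], peaks$hwhm[j]),
    numeric(length(x))))
  pos_area <- pracma::trapz(x, pmax(y - base, 0))
  eaf <- if (pos_area > 0) pracma::trapz(x, model_no_off) / pos_area else NA_real_
  if (quality_warning && is.finite(eaf) && eaf < 0.999)
    warning(sprintf("fit in [%g, %g] explains %.2f%% of the window area (< 99.9%%)",
                    window[1], window[2], 100 * eaf), call. = FALSE)

  structure(list(peaks = peaks, offset = off, baseline_slope = slope,
                 window = window,
                 explained_area_fraction = eaf,
                 residual_rms = sqrt(mean(stats::resid(fit)^2)),
                 converged = TRUE),
            class = "peak_fit")
}

#' @export
print.peak_fit <- function(x, ...) {
  cat(sprintf("<peak_fit> window [%g, %g] cm^-1, explained area %.4f, rms %.3g\n",
              x$window[1], x$window[2], x$explained_area_fraction,
              x$residual_rms))
  print(format(x$peaks, digits = 5))
  invisible(x)
}

pick_initial_centers <- function(x, y, k) {
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] >= y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  idx <- which(is_max)
  idx <- idx[order(-y[idx])]
  cand <- utils::head(idx, k)
  if (length(cand) < k) {
    extra <- setdiff(order(-y), cand)
    cand <- c(cand, utils::head(extra, k - length(cand)))
  }
  sort(x[cand])
}

try_lorentz_nls <- function(x, y, centers, amps, hwhm0, off0, window,
                            linear_baseline = TRUE) {
  k <- length(centers)
  st <- c(stats::setNames(as.list(centers), paste0("c", seq_len(k))),
          stats::setNames(as.list(rep(hwhm0, k)), paste0("g", seq_len(k))),
          stats::setNames(as.list(amps), paste0("A", seq_len(k))),
          list(off = off0),
          if (linear_baseline) list(slope = 0))
  form <- stats::as.formula(paste0(
    "y ~ off + ", if (linear_baseline) "slope * (x - mean(x)) + " else "",
    paste(sprintf("A%d / (1 + ((x - c%d) / g%d)^2)", 1:k, 1:k, 1:k),
          collapse = " + ")))
  fit <- try(suppressWarnings(minpack.lm::nlsLM(
    form, start = st, data = data.frame(x = x, y = y),
    lower = c(rep(window[1], k), rep(0.5, k), rep(0, k), -Inf,
              if (linear_baseline) -Inf),
    upper = c(rep(window[2], k), rep(80, k), rep(Inf, k), Inf,
              if (linear_baseline) Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500))), silent = TRUE)
  if (inherits(fit, "try-error")) NULL else fit
}

# default deconvolution windows; peak positions are canonical band centers
default_fit_windows <- function() {
  list(ch2_bend = list(window = c(1380, 1500), centers = 1440),
       c_eq_c = list(window = c(1600, 1700), centers = 1650),
       ch_stretch = list(window = c(2800, 3100),
                         centers = c(2850, 2885, 2930, 3003)))
}

# fitted area of a single band, or 0 when no peak rises above the
# detection floor (threshold_sigma * noise_sd, interior peaks only so a
# neighboring band's flank does not count as presence)
band_area_or_zero <- function(s, window, center, noise_sd, hwhm = 8,
                              threshold_sigma = 5) {
  a <- interior_peak_amplitude(s, window)
  floor_ <- max(threshold_sigma * noise_sd, 1e-12)
  if (is.na(a$center) || a$amplitude <= floor_) return(0)
  fit <- fit_window(s, window, n_components = 1, init = center,
                    init_hwhm = hwhm, quality_warning = FALSE)
  fit$peaks$area[1]
}

#' Integrated-intensity ratios of the unsaturation marker bands
#'
#' Fits the CH2-bend (1440 cm^-1), C=C-stretch (1650 cm^-1) and olefinic
#' =C-H-stretch (3003 cm^-1) bands in their default windows and returns
#' the area ratios `I1650/I1440` and `I3003/I1440`. Bands with no peak
#' above the detection floor contribute zero area (so a fully saturated
#' lipid reads ratio 0 instead of a fit failure). By contract the input
#' must already be background-subtracted, and spectra failing the protein
#' screen are refused unless `allow_contaminated = TRUE` (logged with a
#' warning), because the amide I band would inflate the 1650 area.
#'
#' @param s a background-subtracted [raman_spectrum()].
#' @param noise_sd noise level in counts; estimated when `NULL`.
#' @param protein_check run [protein_screen()] first (default TRUE).
#' @param allow_contaminated proceed despite a failed screen.
#' @param windows window definitions as in `default_fit_windows()`.
#' @return list with `r1650_1440`, `r3003_1440` (both >= 0), and the
#'   underlying areas `a1440`, `a1650`, `a3003`.
#' @export
intensity_ratios <- function(s, noise_sd = NULL, protein_check = TRUE,
                             allow_contaminated = FALSE,
                             windows = default_fit_windows()) {
  noise_sd <- noise_sd %||% estimate_noise(s)
  if (protein_check) {
    pr <- protein_screen(s, noise_sd)
    if (pr$protein_contaminated) {
      if (!allow_contaminated)
        abort_qc(sprintf("protein bands detected at %s cm^-1; ratio analysis refused",
                         paste(round(pr$protein_bands), collapse = ", ")))
      warning("proceeding despite protein contamination at ",
              paste(round(pr$protein_bands), collapse = ", "), " cm^-1",
              call. = FALSE)
    }
  }
  a1440 <- band_area_or_zero(s, windows$ch2_bend$window,
                             windows$ch2_bend$centers[1], noise_sd)
  if (a1440 <= 0)
    abort_fit("no detectable 1440 cm^-1 band: intensity ratios undefined")
  a1650 <- band_area_or_zero(s, windows$c_eq_c$window,
                             windows$c_eq_c$centers[1], noise_sd)
  a3003 <- ch_stretch_area_3003(s, windows$ch_stretch, noise_sd)
  list(r1650_1440 = a1650 / a1440, r3003_1440 = a3003 / a1440,
       a1440 = a1440, a1650 = a1650, a3003 = a3003)
}

# olefinic component area from the multi-component CH-stretch window
ch_stretch_area_3003 <- function(s, wdef, noise_sd, threshold_sigma = 5) {
  # detection floor for the olefinic shoulder: signal above the local
  # level at 2980-3060 after removing the window median
  i <- window_index(s, c(2980, 3060))
  amp <- max(s$intensity[i]) - stats::median(s$intensity[window_index(s, wdef$window)])
  if (amp <= max(threshold_sigma * noise_sd, 1e-12)) return(0)
  fit <- fit_window(s, wdef$window, n_components = length(wdef$centers),
                    init = wdef$centers, quality_warning = FALSE)
  j <- which.min(abs(fit$peaks$center - 3003))
  if (abs(fit$peaks$center[j] - 3003) > 25) return(0)
  fit$peaks$area[j]
}
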