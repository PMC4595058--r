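#' Band-model constants of the synthetic spectrum generator
#'
#' The generator writes spectra as sums of Lorentzian bands whose areas are
#' tied to molecular structure: the CH2-twist (1300), CH2-bend (1440) and
#' CH2-stretch (2850/2885/2930) areas scale with the number of methylene
#' groups, and the C=C-stretch (1650) and olefinic =C-H-stretch (3003)
#' areas with the number of double bonds. The coupling between the two
#' families is fixed so that at 532 nm the integrated-area ratio
#' `I1650/I1440` equals `coupling * n_double_bonds / n_ch2` exactly;
#' the default `coupling = 7.3` anchors an oleic-like lipid
#' (`n_double_bonds/n_ch2 = 1/14`) at a ratio of 0.52. At 785 nm the
#' coupling is rescaled by `ratio_785_vs_532` to emulate the different
#' instrument response of the NIR arm (a monounsaturated lipid then reads
#' 0.30 instead of 0.52). The 532 nm arm is globally about ten times
#' brighter, and the relative weight of the CH-stretch region makes it the
#' dominant feature under green excitation but a minor one in the NIR.
#'
#' @param excitation_nm 532 or 785.
#' @param coupling area-ratio coupling constant at 532 nm (default 7.3).
#' @param ratio_785_vs_532 NIR/green ratio rescaling (default 0.30/0.52).
#' @param include_cis_band also generate the weak =C-H *cis* deformation
#'   band at 1260 cm^-1. Off by default because it falls inside the amide
#'   III protein-screen window and would make every unsaturated pure lipid
#'   read as protein-contaminated.
#' @return a list of generator constants (see source); mostly internal, but
#'   exported so scripts can state the generator contract explicitly.
#' @export
band_model <- function(excitation_nm = 532, coupling = 7.3,
                       ratio_785_vs_532 = 0.30 / 0.52,
                       include_cis_band = FALSE) {
  if (!excitation_nm %in% c(532, 785))
    stop("unsupported excitation wavelength: ", excitation_nm, " nm")
  green <- excitation_nm == 532
  list(
    excitation_nm = excitation_nm,
    area_unit = 50 * if (green) 10 else 1,   # counts*cm^-1 per structural unit
    coupling = coupling * if (green) 1 else ratio_785_vs_532,
    ch_stretch_scale = if (green) 1.2 else 0.1,
    carotenoid_boost = if (green) 1 else 1.5,
    include_cis_band = include_cis_band,
    lipid_hwhm = 8,
    carotenoid_hwhm = 6,
    bleach_tau = 25   # seconds; photobleach decay constant
  )
}

# component basis spectra on a grid; each column is one weight source
# (n_ch2, n_double_bonds, carotenoid, chlorophyll, protein, fluorescence),
# in counts per unit weight. Bleach decay is applied by the callers.
band_basis <- function(wavenumber, bm) {
  u <- bm$area_unit
  gl <- bm$lipid_hwhm
  gc <- bm$carotenoid_hwhm
  cs <- bm$ch_stretch_scale
  amp <- function(area, g) area / (pi * g)
  L <- function(center, area, g) lorentzian(wavenumber, center, amp(area, g), g)

  b_ch2 <- L(1300, 0.2 * u, gl) + L(1440, 1.0 * u, gl) +
    cs * (L(2850, 0.9 * u, gl) + L(2885, 0.7 * u, gl) + L(2930, 0.5 * u, gl))
  b_db <- L(1650, bm$coupling * u, gl) + cs * L(3003, 3.0 * u, gl)
  if (bm$include_cis_band) b_db <- b_db + L(1260, 0.2 * u, gl)
  b_car <- bm$carotenoid_boost *
    (L(1006, 2 * u, gc) + L(1155, 5 * u, gc) + L(1520, 12 * u, gc))
  b_chl <- L(900, 8 * u, 40) + L(1100, 6 * u, 40)
  b_prot <- L(550, 2 * u, gl) + L(1004, 2.5 * u, 5) +
    L(1245, 1.5 * u, 10) + L(1285, 1.0 * u, 10) + L(1660, 2.0 * u, 10)
  b_fl <- u * (exp(-wavenumber / 1200) + 0.2)

  cbind(n_ch2 = b_ch2, n_double_bonds = b_db, carotenoid = b_car,
        chlorophyll = b_chl, protein = b_prot, fluorescence = b_fl)
}

compose_spectrum <- function(wavenumber, weights, bm, noise_sd = 0,
                             noise_model = c("gaussian", "poisson"),
                             meta = list()) {
  noise_model <- match.arg(noise_model)
  basis <- band_basis(wavenumber, bm)
  y <- drop(basis %*% weights[colnames(basis)])
  if (noise_model == "gaussian") {
    if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  } else {
    y <- stats::rpois(length(y), pmax(y, 0))
  }
  raman_spectrum(wavenumber, y, bm$excitation_nm, meta = meta)
}

#' Simulate the Raman spectrum of a fatty-acid standard
#'
#' A background-free spectrum of a neat standard on the default grid. Band
#' areas follow the generator contract of [band_model()]: in particular the
#' integrated-area ratio `I1650/I1440` is exactly
#' `coupling * n_double_bonds / n_ch2` at zero noise.
#'
#' @param fa a [fatty_acid][parse_fatty_acid] (or a code string).
#' @param excitation_nm 532 or 785.
#' @param noise_sd additive Gaussian noise standard deviation in counts
#'   (default 0.5, the residual detector noise of a spectrum averaged over
#'   the usual 10-25 accumulations).
#' @param seed optional integer; fixes the noise realization without
#'   disturbing the caller's RNG stream.
#' @param wavenumber grid, default [default_wavenumbers()].
#' @param bm generator constants, default `band_model(excitation_nm)`.
#' @param noise_model `"gaussian"` (default, detector-dominated) or
#'   `"poisson"` (shot-noise-dominated).
#' @return a [raman_spectrum()].
#' @examples
#' s <- simulate_standard(parse_fatty_acid("C18:1", 13.4), 532, noise_sd = 0)
#' @export
simulate_standard <- function(fa, excitation_nm = 532, noise_sd = 0.5,
                              seed = NULL, wavenumber = default_wavenumbers(),
                              bm = band_model(excitation_nm),
                              noise_model = "gaussian") {
  if (is.character(fa)) fa <- parse_fatty_acid(fa)
  stopifnot(inherits(fa, "fatty_acid"))
  w <- c(n_ch2 = fa$n_ch2, n_double_bonds = fa$n_double_bonds,
         carotenoid = 0, chlorophyll = 0, protein = 0, fluorescence = 0)
  with_seed(seed, compose_spectrum(
    wavenumber, w, bm, noise_sd, noise_model,
    meta = list(profile = fa$code, excitation_nm = excitation_nm,
                noise_sd = noise_sd, seed = seed %||% NA)))
}

#' Describe a synthetic algal cell
#'
#' Composition of a simulated single cell: a lipid mixture (weight
#' fractions of registry standards) plus pigment, protein and fluorescence
#' interference. The default is an oleic-dominant, pigmented,
#' protein-clean profile emulating a wild-type *C. reinhardtii* (CC-503)
#' lipid body.
#'
#' @param lipids named numeric vector of weight fractions (names are
#'   fatty-acid codes), summing to 1.
#' @param carotenoid,chlorophyll,protein dimensionless interference
#'   weights, >= 0.
#' @param fluorescence autofluorescence baseline weight, >= 0.
#' @param lipid_scale overall lipid amount (scales all lipid bands).
#' @return object of class `cell_profile`.
#' @export
cell_profile <- function(lipids = c("C18:1" = 1), carotenoid = 1,
                         chlorophyll = 1, protein = 0, fluorescence = 30,
                         lipid_scale = 1) {
  if (any(c(carotenoid, chlorophyll, protein, fluorescence, lipid_scale) < 0))
    stop("cell-profile weights must be >= 0")
  counts <- mixture_counts(lipids)
  structure(list(lipids = lipids, counts = counts, carotenoid = carotenoid,
                 chlorophyll = chlorophyll, protein = protein,
                 fluorescence = fluorescence, lipid_scale = lipid_scale),
            class = "cell_profile")
}

#' Simulate a single-cell Raman spectrum
#'
#' Lipid bands as in [simulate_standard()] plus carotenoid resonance bands
#' (1006/1155/1520 cm^-1, enhanced under NIR excitation), broad chlorophyll
#' bands, optional protein bands (550, 1004, amide III doublet, amide I)
#' and a broad fluorescence baseline. Pigment resonance and fluorescence
#' decay exponentially with photobleach time (time constant
#' `band_model()$bleach_tau`, 25 s); protein bands do not bleach.
#'
#' @param profile a [cell_profile()].
#' @param bleach_seconds photobleach pre-exposure in seconds, >= 0.
#' @inheritParams simulate_standard
#' @return a [raman_spectrum()].
#' @export
simulate_cell <- function(profile = cell_profile(), bleach_seconds = 75,
                          excitation_nm = 532, noise_sd = 0.5, seed = NULL,
                          wavenumber = default_wavenumbers(),
                          bm = band_model(excitation_nm),
                          noise_model = "gaussian") {
  stopifnot(inherits(profile, "cell_profile"), bleach_seconds >= 0)
  decay <- exp(-bleach_seconds / bm$bleach_tau)
  w <- c(n_ch2 = profile$counts$n_ch2 * profile$lipid_scale,
         n_double_bonds = profile$counts$n_double_bonds * profile$lipid_scale,
         carotenoid = profile$carotenoid * decay,
         chlorophyll = profile$chlorophyll * decay,
         protein = profile$protein,
         fluorescence = profile$fluorescence * decay)
  with_seed(seed, compose_spectrum(
    wavenumber, w, bm, noise_sd, noise_model,
    meta = list(profile = paste(names(profile$lipids),
                                profile$lipids, sep = "=", collapse = ","),
                bleach_seconds = bleach_seconds,
                excitation_nm = excitation_nm, noise_sd = noise_sd,
                seed = seed %||% NA)))
}
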