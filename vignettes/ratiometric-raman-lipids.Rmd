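---
title: "Ratiometric Raman quantitation of microalgal lipids: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratiometric Raman quantitation of microalgal lipids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanlipids)
```

## The measurement model

Raman band intensities of lipids scale with the number of vibrating
groups: the CH₂-bend band at 1440 cm⁻¹ with the count of aliphatic
methylene groups (N_CH₂) and the C=C-stretch band at 1650 cm⁻¹ with the
count of carbon–carbon double bonds (N_C=C). Absolute intensities are
unusable in cellular samples (focus, fluorescence, cross-sections), but
the *ratio* of integrated band areas,

$$ r = \frac{I_{1650}}{I_{1440}} \;\propto\; \frac{N_{C=C}}{N_{CH_2}}, $$

is robust, and maps linearly onto both the double-bond count and the
chain-normalized unsaturation of the lipid, and sigmoidally onto its
melting point. Band areas are obtained by deconvolution with Lorentzian
lineshapes $A/(1+((\nu-\nu_0)/\gamma)^2)$; the "integrated peak
intensity" is the exact integral $\pi A \gamma$, never the peak height.
The olefinic =C–H stretch near 3003 cm⁻¹ provides a second, concordant
unsaturation ratio ($I_{3003}/I_{1440}$) used as a cross-check.

For a straight-chain, methylene-interrupted free fatty acid C$n$:$k$,

$$ N_{CH_2} = n - 2 - 2k, $$

since the carboxyl and terminal methyl carbons are not methylenes and
each *cis* double bond converts two of them to =CH–. The registry of
eleven even-chain standards (C12:0 … C22:6, zero to six double bonds,
literature melting points) spans the calibration range; the identity of
the panel is a documented choice of fatty acids common in microalgal
extracts, user-overridable via a text table.

## What the generator emulates — and what it does not

`simulate_standard()` and `simulate_cell()` write spectra as sums of
Lorentzian bands on a 0–3399 cm⁻¹ grid at 3 cm⁻¹ spacing. The generator's
contract is that at 532 nm the area ratio $I_{1650}/I_{1440}$ equals
$7.3\,N_{C=C}/N_{CH_2}$ *exactly* at zero noise. The coupling constant
7.3 anchors an oleic-like lipid ($1/14$) at a ratio of 0.52, the measured
wild-type *C. reinhardtii* value; at 785 nm the coupling is rescaled by
$0.30/0.52$ so the same cell reads 0.30, reproducing the two-laser
disparity of the instrument response. Per-laser intensity regimes follow
the observed phenomenology: the 532 nm arm is globally ~10× brighter and
dominated by the CH-stretch cluster (2850/2885/2930 cm⁻¹), while at
785 nm the 1440 cm⁻¹ band dominates and carotenoid resonance is boosted
(×1.5).

Cells add carotenoid bands (1006, 1155, 1520 cm⁻¹; half-width 6 cm⁻¹),
broad chlorophyll features (≈900, ≈1100 cm⁻¹), optional protein bands
(550, 1004, 1245/1285 amide III, 1660 amide I) and a broad decaying-
exponential fluorescence baseline. Pigment resonance and fluorescence
decay as $e^{-t/\tau}$ with photobleach time $t$ and $\tau = 25$ s, so a
75 s bleach (the long end of practical bleaching) suppresses them to
≈5 %; protein bands do not bleach. Noise is additive Gaussian with a
default of 0.5 counts — the residual noise of a spectrum averaged over
the usual 10–25 accumulations (a Poisson switch exists for
shot-noise-dominated scenarios). Lipid band half-widths default to
8 cm⁻¹, carotenoids to 6 cm⁻¹, typical condensed-phase values.

The =C–H *cis* deformation band (1260 cm⁻¹) is **not** generated by
default: it falls inside the amide III protein-screen window, and with it
every unsaturated pure lipid would read as protein-contaminated. It can
be enabled via `band_model(include_cis_band = TRUE)` when the screen is
not in play. Chlorophyll's congested 1400–1500 cm⁻¹ contributions are
likewise not modeled; in real spectra they add variance to the 1440
window that the synthetic tests do not probe. More generally, passing
tests on this generator demonstrates the *pipeline's* correctness under
the stated band model — not that real algal spectra obey that model;
cross-sections, resonance effects and matrix backgrounds are outside its
scope.

Hyperspectral scenes are continuous 2D descriptions (droplets, pigment
patches, uniform backgrounds) rendered through a Gaussian lateral PSF
(FWHM $0.42\lambda/\mathrm{NA}$) at any pixel density, which is what lets
the localization loop re-scan the same scene at finer windows. Droplets
are spherical bodies: their projected signal is the chord-length profile
$\sqrt{1-(d/R)^2}$, peaked at the center, so "highest integrated
intensity" has a well-defined location. The z-dimension is deliberately
absent — axial sectioning is an instrument action, and scenes model the
in-focus plane only.

## Acquisition hygiene

**Background subtraction** is a centered moving average subtracted from
the spectrum (reflect-padded edges), applied with the *same* window to
standards and unknowns. The default window is 600 cm⁻¹ (~200 grid
points). The width matters more than it looks: with a window comparable
to the analysis windows (e.g. 300 cm⁻¹), a strong neighbor band such as
the 1650 cm⁻¹ band of a polyunsaturated standard enters and leaves the
average *within* the 1440 cm⁻¹ fit window, leaving a composition-
dependent hook that biased measured ratios by up to −12 % (C22:6) in our
calibration runs. At 600 cm⁻¹ each strong band's contribution to the
average is constant across the neighboring fit windows, the residual
distortion collapses to a flat pedestal absorbed by the fit's offset
term, and all eleven standards read within ~1 % of the generator
contract. The window remains configurable; whatever value is chosen must
be held fixed across a calibration and its unknowns.

**Protein screen.** The 1650 cm⁻¹ analysis band overlaps protein amide I,
so spectra are admitted only when free of the *other* protein markers:
550 ± 10 (disulfide), 1004 ± 5 (phenylalanine) and 1220–1300 cm⁻¹
(amide III), each flagged when a peak exceeds 5σ of the noise. In the
wide amide III window only *interior* local maxima count — the rising
flank of the adjacent 1300 cm⁻¹ CH₂-twist band must not register — and
amplitudes are measured against a straight baseline between the window
ends so smooth residual background does not trip the threshold.
Quantitation refuses contaminated spectra rather than attempting to fit
an amide I component under 1650; an explicit override exists and logs a
warning.

**Photobleach check.** "Carotenoid far below the lipid bands" is
quantified as area(1520) < 0.5 × min(area(1440), area(1650)). The 0.5 is
a documented, configurable choice; an unbleached default cell fails it by
~3× and a 75 s bleach passes it by ~6×, so the decision is insensitive to
the exact threshold within a factor of a few.

## Deconvolution

`fit_window()` performs Levenberg–Marquardt least squares of a sum of
Lorentzians plus a local linear baseline, with bounded parameters
(centers inside the window, γ ∈ [0.5, 80] cm⁻¹, amplitudes ≥ 0),
initialized at canonical band centers with γ = 8 cm⁻¹ and local-maximum
amplitudes, and up to five seeded random-perturbation restarts on
non-convergence. Default windows: 1380–1500 (CH₂ bend), 1600–1700 (C=C),
2800–3100 cm⁻¹ (CH stretches 2850/2885/2930 plus olefinic 3003). The
explained-area fraction (model area over positive signal area in the
window) is reported and warned about below 0.999, mirroring the ≥ 99.9 %
fitting-quality convention — a report, not a hard gate. Band *presence*
is decided before fitting: a band whose interior peak amplitude stays
under 5σ contributes zero area, which is how a fully saturated standard
reads ratio 0 instead of producing a degenerate fit.

## Calibration and inversion

Three relations are fitted per excitation wavelength (models carry an
excitation tag that `quantify()` enforces):

- **ratio ↔ C=C count** and **ratio ↔ N_C=C/N_CH₂**: ordinary least
  squares. An eight-strain reference panel of measured ratios and derived
  values provides a measurement-anchored surrogate (slope ≈ 1.64,
  intercept ≈ −0.045 for the C=C relation).
- **ratio ↔ melting point**: a four-parameter logistic, decreasing in
  melting point. Because this model exists solely for *inverse*
  prediction (melting point from a measured ratio), the least-squares
  objective is formulated in the melting-point direction — i.e.
  parameters minimize the error of the inverse curve at the calibration
  points, via seeded multistart Nelder–Mead — and $r^2$ is reported in
  that direction. Fitted in the ratio direction instead, the saturated
  shelf (four standards with ratio 0 between 44 and 69 °C) dominates the
  loss and the inverted melting point at ratio 0.52 lands near 0 °C; in
  the inverse-prediction direction it lands at ≈ 10.7 °C, between the
  palmitoleic (−0.1 °C) and oleic (13.4 °C) anchors, which is the
  physically sensible interpolation. Inversion is range-guarded:
  ratios at or beyond the fitted asymptotes raise an error.

Negative property estimates (possible at near-zero ratios through the
OLS intercept) are clipped to zero with a warning. Non-integer
double-bond estimates are meaningful: they indicate fatty-acid mixtures,
and `mixture_ratio()` provides the closed-form expectation
$r = 7.3\,\frac{\sum_i m_i k_i}{\sum_i m_i N_{CH_2,i}}$ with mole
fractions $m_i \propto w_i / MW_i$ for weight fractions $w_i$ — always
between the pure-component ratios and monotone in composition.

**Parameter recovery.** For standards of known chain length, the
double-bond count is recovered as est(N_C=C/N_CH₂) × N_CH₂. The pooled
linear C=C-vs-ratio model is *not* used for this check: under the
generator contract the ratio is proportional to N_C=C/N_CH₂, so panel
points with different chain lengths are not collinear in (ratio, C=C)
space and the pooled line carries structural scatter of up to ±0.24
C=C at the saturated end — real, chain-length-driven dispersion, not a
fitting defect. Recovery through the chain-normalized route is exact up
to noise; at a noise level of 2 % of the 1440-band amplitude, the
per-standard mean over 20 replicates recovers every registry standard
within ±0.05 of its integer double-bond count (single replicates of
C22:6 scatter with sd ≈ 0.16, since a 2 % ratio error is already 0.1 in
C=C units there).

**Population classification** thresholds estimated C=C at 0.35 / 0.65 —
midpoints between the saturated (0), mixed (~0.5) and monounsaturated
(~1) archetypes — and reports the class histogram. Thresholds are
configurable.

## Localization in hyperspectral maps

The guided-scan loop mirrors acquisition practice: a 10 × 10 survey scan
over the current window, a lipid band-integral image (2800–3000 cm⁻¹
under 532 nm where CH stretches dominate; 1380–1500 cm⁻¹ under 785 nm),
re-centering on the maximum pixel, then halving the window until it is
≤ 1 µm — hence exactly $\lceil \log_2(\mathrm{start}/\mathrm{stop})
\rceil$ iterations, five for a 20 µm start. Ties at the image maximum
break deterministically to the lowest (row, column) index; a first image
with no pixel above the noise floor (max − median ≤ 5 × MAD) is a
localization failure, which is also how degenerate uniform scenes are
rejected. Over 50 random scenes with a 1.5 µm droplet the final center
lands within 0.4 µm of truth on both lasers (the droplet radius is chosen
comparable to the 2 µm survey pitch, as for a mature algal lipid body —
features much smaller than the pitch can fall between sampling points of
*any* coarse scan, on the instrument as in the model). Optics helpers use
the Airy diameter $1.22\lambda/\mathrm{NA}$ for spot size and
$0.42\lambda/\mathrm{NA}$ for lateral resolution, the constant that
reproduces the instrument's printed values at both wavelengths; axial
resolution is not implemented because no single textbook constant
reproduces the printed axial pair, and nothing downstream needs it.

## Numerical and scale choices

Tests and the acceptance script run on the full 1134-point grid with
10 × 10 scans, 5 localization iterations, 20-replicate recovery panels,
50 localization trials and 30-cell populations; the whole suite completes
in about a minute on one core. Determinism: every stochastic step takes a
seed, simulation helpers restore the caller's RNG state, and identical
seeds reproduce outputs bit-for-bit. Text formats carry 12 significant
digits so write/read round trips are exact at that precision.

## Known limitations

- The band model is phenomenological: fixed Lorentzian widths, scalar
  per-laser scale factors, no resonance line-shape effects, no
  wavenumber calibration drift.
- The protein screen tests three marker windows only; a protein whose
  signature lies elsewhere would pass it.
- The eight-strain reference calibration is a surrogate anchored in
  published per-strain measurements, not a re-measurement of the
  eleven-standard panel; the synthetic-panel calibrations carry the
  generator's coupling constant by construction.
- Scenes are 2D; axial structure, scattering and cell-to-cell optical
  variability are not modeled.
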