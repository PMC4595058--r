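# Independent oracles used across the suite. These deliberately avoid the
# package's own closed forms: structures are built atom by atom and areas
# are integrated numerically on fine grids.

# Build an explicit atom list for a straight-chain, methylene-interrupted
# (omega-3 family) free fatty acid: one row per carbon with its hydrogen
# count and hybridization. Double bond i (i = 1..n_db) joins carbons
# (n - 3i, n - 3i + 1), counted from the carboxyl carbon C1.
fa_atom_list <- function(n_carbons, n_double_bonds) {
  stopifnot(n_carbons >= 4,
            n_double_bonds == 0 || n_carbons - 3 * n_double_bonds >= 2)
  sp2 <- logical(n_carbons)
  for (i in seq_len(n_double_bonds)) {
    a <- n_carbons - 3 * i
    sp2[c(a, a + 1)] <- TRUE
  }
  h <- integer(n_carbons)
  h[1] <- 0                                   # carboxyl carbon: no C-H
  for (k in 2:(n_carbons - 1)) h[k] <- if (sp2[k]) 1L else 2L
  h[n_carbons] <- 3L                          # terminal methyl
  data.frame(carbon = seq_len(n_carbons), h = h, sp2 = sp2)
}

# brute-force CH2 count: interior sp3 carbons carrying exactly two hydrogens
count_ch2_oracle <- function(n_carbons, n_double_bonds) {
  atoms <- fa_atom_list(n_carbons, n_double_bonds)
  sum(!atoms$sp2 & atoms$h == 2L & atoms$carbon != 1L)
}

# molecular weight from the atom list: C H O2, plus the carboxyl OH proton
mw_oracle <- function(n_carbons, n_double_bonds) {
  atoms <- fa_atom_list(n_carbons, n_double_bonds)
  12.011 * n_carbons + 1.008 * (sum(atoms$h) + 1) + 2 * 15.999
}

# fine-grid numeric integral of one Lorentzian component over (wide) support
numeric_lorentz_area <- function(center, amplitude, hwhm,
                                 halfspan = 4000, dx = 0.05) {
  x <- seq(center - halfspan, center + halfspan, by = dx)
  pracma::trapz(x, amplitude / (1 + ((x - center) / hwhm)^2))
}

# intensity_ratios with the QC chatter silenced (synthetic inputs are
# protein-free by construction unless a test says otherwise)
quiet_ratios <- function(s, ...) {
  suppressWarnings(intensity_ratios(s, protein_check = FALSE, ...))
}

oleic <- function() parse_fatty_acid("C18:1", 13.4)

# registry lookup by code
registry_fa <- function(code) {
  reg <- standard_registry()
  reg[[which(vapply(reg, `[[`, "", "code") == code)]]
}
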