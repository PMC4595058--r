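#' Read and write spectra as two-column delimited text
#'
#' The on-disk format is plain text: `#`-prefixed `key: value` header
#' lines (at least `excitation_nm`), then two whitespace-separated columns
#' of wavenumber (cm^-1) and intensity (counts). Values are written with
#' 12 significant digits, so a write/read round trip is exact at that
#' precision. Format violations raise errors naming the offending line.
#'
#' @param path file path.
#' @param s a [raman_spectrum()].
#' @return `read_spectrum()`: a [raman_spectrum()]; `write_spectrum()`:
#'   `path`, invisibly.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- parse_kv(sub("^#\\s*", "", lines[hdr]))
  body_idx <- which(!hdr & nzchar(trimws(lines)))
  fields <- strsplit(trimws(lines[body_idx]), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 2))
    abort_format(sprintf("%s: line %d has %d fields, expected 2",
                         path, body_idx[which(nf != 2)[1]], nf[nf != 2][1]))
  wn <- as.numeric(vapply(fields, `[`, "", 1))
  y <- as.numeric(vapply(fields, `[`, "", 2))
  if (anyNA(wn) || anyNA(y))
    abort_format(sprintf("%s: non-numeric value at line %d", path,
                         body_idx[which(is.na(wn) | is.na(y))[1]]))
  bad <- which(diff(wn) <= 0)
  if (length(bad))
    abort_format(sprintf("%s: wavenumber axis not strictly increasing at line %d",
                         path, body_idx[bad[1] + 1]))
  if (is.null(meta$excitation_nm))
    abort_format(sprintf("%s: missing required header '# excitation_nm: ...'", path))
  ex <- as.numeric(meta$excitation_nm)
  raman_spectrum(wn, y, ex, meta = meta[names(meta) != "excitation_nm"])
}

#' @rdname read_spectrum
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "raman_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# excitation_nm: %g", s$excitation_nm), con)
  for (k in setdiff(names(s$meta), "excitation_nm"))
    writeLines(sprintf("# %s: %s", k, format(s$meta[[k]])), con)
  writeLines(sprintf("%.12g %.12g", s$wavenumber, s$intensity), con)
  invisible(path)
}

parse_kv <- function(lines) {
  lines <- lines[grepl(":", lines, fixed = TRUE)]
  keys <- trimws(sub(":.*$", "", lines))
  vals <- trimws(sub("^[^:]*:", "", lines))
  stats::setNames(as.list(vals), keys)
}

write_kv <- function(kv, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  for (k in names(kv))
    writeLines(sprintf("%s: %s", k, format(kv[[k]], digits = 12)), con)
  invisible(path)
}

#' Read and write hypercubes as long-format text
#'
#' The cube itself is a four-column table (`x_idx`, `y_idx`,
#' `wavenumber_cm1`, `intensity`); the grid geometry lives in a sidecar
#' `key: value` text file (`nx`, `ny`, `step_um`, `origin_x_um`,
#' `origin_y_um`, `excitation_nm`). Every pixel must appear exactly once
#' per wavenumber; missing or duplicated pixels are reported by index.
#'
#' @param path data table path.
#' @param sidecar sidecar metadata path.
#' @param h a [hypercube()].
#' @return `read_hypercube()`: a [hypercube()]; `write_hypercube()`:
#'   `path`, invisibly.
#' @export
read_hypercube <- function(path, sidecar) {
  meta <- parse_kv(sub("^#\\s*", "", readLines(sidecar)))
  need <- c("nx", "ny", "step_um", "origin_x_um", "origin_y_um", "excitation_nm")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    abort_format(sprintf("%s: missing sidecar keys: %s", sidecar,
                         paste(miss, collapse = ", ")))
  nx <- as.integer(meta$nx); ny <- as.integer(meta$ny)
  tab <- utils::read.table(path, header = TRUE, comment.char = "#")
  if (!all(c("x_idx", "y_idx", "wavenumber_cm1", "intensity") %in% names(tab)))
    abort_format(sprintf("%s: expected columns x_idx, y_idx, wavenumber_cm1, intensity", path))
  wn <- sort(unique(tab$wavenumber_cm1))
  counts <- table(factor(tab$x_idx, levels = 1:nx),
                  factor(tab$y_idx, levels = 1:ny))
  bad <- which(counts != length(wn), arr.ind = TRUE)
  if (nrow(bad))
    abort_format(sprintf(
      "%s: pixel (%s) has %d rows, expected %d (missing or duplicate entries)",
      path, paste(bad[1, ], collapse = ","),
      counts[bad[1, 1], bad[1, 2]], length(wn)))
  if (nrow(tab) != nx * ny * length(wn))
    abort_format(sprintf("%s: table shape does not match sidecar nx*ny", path))
  intens <- matrix(NA_real_, nx * ny, length(wn))
  ord <- order(tab$y_idx, tab$x_idx, tab$wavenumber_cm1)
  tab <- tab[ord, ]
  intens[] <- matrix(tab$intensity, nrow = nx * ny, byrow = TRUE)
  hypercube(intens, nx, ny, as.numeric(meta$step_um),
            c(as.numeric(meta$origin_x_um), as.numeric(meta$origin_y_um)),
            wn, as.numeric(meta$excitation_nm))
}

#' @rdname read_hypercube
#' @export
write_hypercube <- function(h, path, sidecar) {
  stopifnot(inherits(h, "hypercube"))
  nwn <- length(h$wavenumber)
  pix <- expand.grid(x_idx = seq_len(h$nx), y_idx = seq_len(h$ny))
  tab <- data.frame(
    x_idx = rep(pix$x_idx, each = nwn),
    y_idx = rep(pix$y_idx, each = nwn),
    wavenumber_cm1 = rep(h$wavenumber, h$nx * h$ny),
    intensity = as.numeric(t(h$intensity))
  )
  utils::write.table(format(tab, digits = 12, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  write_kv(list(nx = h$nx, ny = h$ny, step_um = h$step,
                origin_x_um = h$origin[1], origin_y_um = h$origin[2],
                excitation_nm = h$excitation_nm),
           sidecar, header = "hypercube sidecar")
  invisible(path)
}

#' Serialize calibration models as key-value text
#'
#' @param model a [calibration_model][fit_linear].
#' @param path file path.
#' @return `read_calibration()`: the model; `write_calibration()`:
#'   `path`, invisibly.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  kv <- c(list(kind = model$kind, x_label = model$x_label,
               y_label = model$y_label, excitation_nm = model$excitation_nm,
               r_squared = model$r_squared, n_points = model$n_points),
          as.list(model$params))
  write_kv(kv, path, header = "calibration model")
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  kv <- parse_kv(sub("^#\\s*", "", readLines(path)))
  need <- c("kind", "excitation_nm", "r_squared", "n_points")
  if (!all(need %in% names(kv)))
    abort_format(sprintf("%s: not a calibration model file", path))
  pnames <- switch(kv$kind,
                   linear = c("slope", "intercept"),
                   sigmoid4PL = c("lower", "upper", "midpoint", "scale"),
                   abort_format(sprintf("%s: unknown model kind '%s'", path, kv$kind)))
  if (!all(pnames %in% names(kv)))
    abort_format(sprintf("%s: missing parameters for kind '%s'", path, kv$kind))
  new_calibration(kind = kv$kind,
                  params = stats::setNames(as.numeric(kv[pnames]), pnames),
                  x_label = kv$x_label %||% "x", y_label = kv$y_label %||% "y",
                  excitation_nm = as.numeric(kv$excitation_nm),
                  r_squared = as.numeric(kv$r_squared),
                  n_points = as.integer(kv$n_points))
}

# run configuration -----------------------------------------------------------

#' Run configuration
#'
#' A flat `key: value` text file controlling grid, windows, thresholds,
#' generator constants and the seed. `default_config()` lists every known
#' key with its default; unknown keys in a file are errors.
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(
    grid_min_cm1 = 0, grid_max_cm1 = 3399, grid_step_cm1 = 3,
    background_window_cm1 = 600,
    protein_threshold_sigma = 5,
    photobleach_max_ratio = 0.5,
    ratio_coupling = 7.3,
    bleach_tau_s = 25,
    noise_sd = 0.5,
    class_threshold_low = 0.35,
    class_threshold_high = 0.65,
    seed = 1
  )
}

#' @param path config file path.
#' @rdname default_config
#' @export
read_config <- function(path) {
  cfg <- default_config()
  kv <- parse_kv(sub("^#\\s*", "", readLines(path)))
  unknown <- setdiff(names(kv), names(cfg))
  if (length(unknown))
    abort_format(sprintf("%s: unknown config keys: %s", path,
                         paste(unknown, collapse = ", ")))
  for (k in names(kv)) cfg[[k]] <- as.numeric(kv[[k]])
  cfg
}

#' @param cfg configuration list.
#' @rdname default_config
#' @export
write_config <- function(cfg, path) {
  write_kv(cfg, path, header = "ramanlipids run configuration")
}
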