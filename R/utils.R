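# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Lorentzian lineshape
#'
#' `A / (1 + ((x - x0) / gamma)^2)`; its exact integral over the real line is
#' `pi * A * gamma`, the "integrated peak intensity" used throughout the
#' ratiometric analysis.
#'
#' @param x numeric vector (wavenumbers, cm^-1).
#' @param center peak center x0 (cm^-1).
#' @param amplitude peak height A (counts).
#' @param hwhm half width at half maximum gamma (cm^-1), > 0.
#' @return numeric vector of the same length as `x`.
#' @export
lorentzian <- function(x, center, amplitude, hwhm) {
  stopifnot(hwhm > 0)
  amplitude / (1 + ((x - center) / hwhm)^2)
}

#' Exact area of a Lorentzian peak
#'
#' @param amplitude peak height (counts).
#' @param hwhm half width at half maximum (cm^-1).
#' @return area in counts * cm^-1 (`pi * amplitude * hwhm`).
#' @export
lorentzian_area <- function(amplitude, hwhm) pi * amplitude * hwhm

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
# seed = NULL leaves the global stream untouched (and advances it).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# condition constructors used for CLI exit-code mapping
abort_format <- function(msg) {
  stop(structure(class = c("rl_format_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

abort_fit <- function(msg) {
  stop(structure(class = c("rl_fit_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

abort_qc <- function(msg) {
  stop(structure(class = c("rl_qc_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
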