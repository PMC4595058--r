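#' Linear ratio calibration
#'
#' Ordinary least squares of a lipid property (number of C=C bonds, or the
#' chain-normalized unsaturation N_C=C/N_CH2) on the `I1650/I1440`
#' intensity ratio.
#'
#' @param x intensity ratios (predictor).
#' @param y property values (response).
#' @param x_label,y_label labels documenting the semantics.
#' @param excitation_nm the excitation wavelength the calibration was
#'   measured at; [quantify()] enforces agreement with the spectrum.
#' @return object of class `calibration_model` with `kind = "linear"`,
#'   `params` (`slope`, `intercept`), `r_squared`, `n_points`.
#' @export
fit_linear <- function(x, y, x_label = "I1650/I1440", y_label = "property",
                       excitation_nm = 532) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2) stop("linear calibration needs at least 2 points")
  if (diff(range(x)) <= .Machine$double.eps)
    stop("degenerate calibration: all x values equal")
  fit <- stats::lm(y ~ x)
  r2 <- if (length(x) > 2)
    suppressWarnings(summary(fit)$r.squared)   # exact fits warn harmlessly
  else 1
  new_calibration(kind = "linear",
                  params = c(slope = unname(stats::coef(fit)[2]),
                             intercept = unname(stats::coef(fit)[1])),
                  x_label = x_label, y_label = y_label,
                  excitation_nm = excitation_nm,
                  r_squared = r2, n_points = length(x))
}

#' Sigmoidal melting-point calibration
#'
#' The intensity ratio falls sigmoidally with the melting point of the
#' lipid: highly unsaturated, low-melting acids sit on the upper branch
#' and saturated, high-melting acids on the lower asymptote. A
#' four-parameter logistic
#' `ratio = lo + (hi - lo) / (1 + exp((mp - mid) / scale))`
#' (monotone decreasing for `scale > 0`) is fitted. Because the model's
#' whole purpose is inverse prediction — reading a melting point off a
#' measured ratio — the least-squares objective is formulated in the
#' melting-point direction: parameters minimize the squared error of
#' `invert_calibration()` at the calibration points, via seeded
#' multi-start Nelder-Mead. `r_squared` is likewise reported in the
#' melting-point direction.
#'
#' @param melting_point melting points in degrees Celsius.
#' @param ratio measured `I1650/I1440` ratios.
#' @param n_starts number of random restarts (first start is
#'   deterministic).
#' @param seed seed for the restarts.
#' @inheritParams fit_linear
#' @return `calibration_model` with `kind = "sigmoid4PL"`, `params`
#'   (`lower`, `upper`, `midpoint`, `scale`).
#' @export
fit_sigmoid_mp <- function(melting_point, ratio, excitation_nm = 532,
                           n_starts = 8, seed = 1) {
  stopifnot(length(melting_point) == length(ratio))
  if (length(ratio) < 5)
    stop("sigmoid calibration needs at least 5 points spanning both asymptotes")
  y <- ratio
  mp <- melting_point
  ymax <- max(y); ymin <- min(y)
  if (ymax - ymin <= .Machine$double.eps) stop("degenerate ratios")

  obj <- function(p) {
    lo <- p[1]; hi <- p[2]; mid <- p[3]; sc <- p[4]
    if (sc <= 0 || hi <= ymax || lo >= ymin) return(1e12)
    z <- (hi - lo) / (y - lo) - 1
    if (any(z <= 0)) return(1e12)
    sum((mp - (mid + sc * log(z)))^2)
  }
  starts <- with_seed(seed, {
    s0 <- c(ymin - 0.05 * (ymax - ymin), 1.2 * ymax, stats::median(mp), 10)
    rest <- replicate(n_starts - 1, c(
      ymin - stats::runif(1, 0.01, 0.3) * (ymax - ymin),
      ymax * stats::runif(1, 1.05, 2),
      stats::runif(1, min(mp), max(mp)),
      stats::runif(1, 3, 30)))
    cbind(s0, rest)
  })
  best <- NULL
  for (j in seq_len(ncol(starts))) {
    o <- stats::optim(starts[, j], obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
    o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  p <- best$par
  if (p[2] <= p[1])
    abort_fit("sigmoid calibration degenerate: upper asymptote below lower")
  mp_hat <- p[3] + p[4] * log((p[2] - p[1]) / (y - p[1]) - 1)
  r2 <- 1 - sum((mp - mp_hat)^2) / sum((mp - mean(mp))^2)
  new_calibration(kind = "sigmoid4PL",
                  params = c(lower = unname(p[1]), upper = unname(p[2]),
                             midpoint = unname(p[3]), scale = unname(p[4])),
                  x_label = "melting point (degC)", y_label = "I1650/I1440",
                  excitation_nm = excitation_nm,
                  r_squared = r2, n_points = length(y))
}

new_calibration <- function(kind, params, x_label, y_label, excitation_nm,
                            r_squared, n_points) {
  structure(list(kind = kind, params = params, x_label = x_label,
                 y_label = y_label, excitation_nm = excitation_nm,
                 r_squared = r_squared, n_points = n_points),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> %s: %s ~ %s (%g nm), r^2 = %.4f, n = %d\n",
              x$kind, x$y_label, x$x_label, x$excitation_nm, x$r_squared,
              x$n_points))
  print(round(x$params, 6))
  invisible(x)
}

#' Predict and invert calibration models
#'
#' `predict_calibration()` maps x to y (`slope * x + intercept` for linear
#' models, the 4PL curve for the melting-point model);
#' `invert_calibration()` maps y back to x on the monotone branch. For the
#' 4PL model, values at or beyond the asymptotes have no finite preimage
#' and raise a range-limit error.
#'
#' @param model a `calibration_model`.
#' @param x,y numeric values.
#' @return numeric vector.
#' @export
predict_calibration <- function(model, x) {
  stopifnot(inherits(model, "calibration_model"))
  p <- model$params
  switch(model$kind,
         linear = p[["slope"]] * x + p[["intercept"]],
         sigmoid4PL = p[["lower"]] + (p[["upper"]] - p[["lower"]]) /
           (1 + exp((x - p[["midpoint"]]) / p[["scale"]])),
         stop("unknown model kind: ", model$kind))
}

#' @rdname predict_calibration
#' @export
invert_calibration <- function(model, y) {
  stopifnot(inherits(model, "calibration_model"))
  p <- model$params
  switch(model$kind,
         linear = {
           if (abs(p[["slope"]]) <= .Machine$double.eps)
             stop("cannot invert a zero-slope calibration")
           (y - p[["intercept"]]) / p[["slope"]]
         },
         sigmoid4PL = {
           if (any(y <= p[["lower"]] | y >= p[["upper"]]))
             stop(sprintf(
               "ratio %s outside the invertible range (%.4g, %.4g) of the sigmoid calibration",
               paste(format(y), collapse = ", "), p[["lower"]], p[["upper"]]))
           p[["midpoint"]] + p[["scale"]] *
             log((p[["upper"]] - p[["lower"]]) / (y - p[["lower"]]) - 1)
         },
         stop("unknown model kind: ", model$kind))
}

#' Build the full calibration set from simulated standards
#'
#' Simulates every registry standard at the given excitation, runs it
#' through the measurement pipeline (optional background subtraction, then
#' [intensity_ratios()]), and fits the three calibration relations:
#' ratio vs number of C=C bonds (linear), ratio vs N_C=C/N_CH2 (linear),
#' and ratio vs melting point (4PL sigmoid).
#'
#' @param standards list of fatty acids, default [standard_registry()].
#' @param excitation_nm 532 or 785.
#' @param noise_sd simulated detector noise (counts).
#' @param seed seed controlling the simulated noise.
#' @param preprocess apply [subtract_background()] before fitting, with
#'   the same window used for unknowns.
#' @param background_window_cm1 moving-average window (cm^-1).
#' @return list with elements `c_bonds`, `n_ratio`, `mp`
#'   (calibration models) and `measurements` (data frame of per-standard
#'   measured ratios).
#' @export
calibrate_panel <- function(standards = standard_registry(),
                            excitation_nm = 532, noise_sd = 0.5, seed = 1,
                            preprocess = TRUE,
                            background_window_cm1 = 600) {
  meas <- lapply(seq_along(standards), function(i) {
    fa <- standards[[i]]
    s <- simulate_standard(fa, excitation_nm, noise_sd = noise_sd,
                           seed = seed + i)
    if (preprocess) s <- subtract_background(s, background_window_cm1)
    r <- suppressWarnings(
      intensity_ratios(s, noise_sd = max(noise_sd, 1e-9),
                       protein_check = FALSE))
    data.frame(code = fa$code, n_double_bonds = fa$n_double_bonds,
               n_ratio = fa$n_double_bonds / fa$n_ch2,
               melting_point = fa$melting_point,
               r1650_1440 = r$r1650_1440, r3003_1440 = r$r3003_1440)
  })
  meas <- do.call(rbind, meas)
  list(
    c_bonds = fit_linear(meas$r1650_1440, meas$n_double_bonds,
                         y_label = "number of C=C bonds",
                         excitation_nm = excitation_nm),
    n_ratio = fit_linear(meas$r1650_1440, meas$n_ratio,
                         y_label = "N_C=C/N_CH2",
                         excitation_nm = excitation_nm),
    mp = fit_sigmoid_mp(meas$melting_point, meas$r1650_1440,
                        excitation_nm = excitation_nm),
    measurements = meas
  )
}

#' Reference panel of algal isolates
#'
#' Measured `I1650/I1440` intensity ratios and the derived number of C=C
#' bonds and N_C=C/N_CH2 for eight algal strains (environmental isolates
#' plus the *C. reinhardtii* CC-503 reference), 532 nm excitation. Used to
#' build surrogate linear calibrations anchored in real measurements.
#'
#' @return data frame with columns `strain`, `ratio`, `c_double_bonds`,
#'   `n_ratio`.
#' @export
reference_isolates <- function() {
  data.frame(
    strain = c("Chloroidium sp. DN1", "Dunaliella sp. DN1", "MG8",
               "Picochloris sp. DN1", "RSSF", "Chlamydomonas sp. KSA1",
               "Chlamydomonas reinhardtii CC-503", "Chlamydomonas sp. HC1"),
    ratio = c(0.55, 0.57, 0.48, 0.75, 1.07, 0.79, 0.52, 1.04),
    c_double_bonds = c(0.86, 0.89, 0.74, 1.17, 1.70, 1.30, 0.80, 1.66),
    n_ratio = c(0.08, 0.08, 0.07, 0.11, 0.15, 0.11, 0.07, 0.15),
    stringsAsFactors = FALSE
  )
}

#' Linear calibrations fitted to the reference isolate panel
#'
#' @param excitation_nm excitation tag for the returned models (the panel
#'   was measured at 532 nm).
#' @return list with `c_bonds` and `n_ratio` calibration models.
#' @export
isolate_calibration <- function(excitation_nm = 532) {
  tab <- reference_isolates()
  list(c_bonds = fit_linear(tab$ratio, tab$c_double_bonds,
                            y_label = "number of C=C bonds",
                            excitation_nm = excitation_nm),
       n_ratio = fit_linear(tab$ratio, tab$n_ratio,
                            y_label = "N_C=C/N_CH2",
                            excitation_nm = excitation_nm))
}

#' Quantify the lipid content of a spectrum
#'
#' Measures the intensity ratios and applies the calibration models:
#' predicts the (possibly fractional) number of C=C bonds and
#' N_C=C/N_CH2 from the linear models, and inverts the sigmoid model for
#' the melting point. Non-integer double-bond estimates indicate a
#' mixture of fatty acids. Physically impossible negative property
#' estimates (arising from the OLS intercept) are clipped to zero with a
#' warning.
#'
#' @param s a background-subtracted [raman_spectrum()] that passes QC.
#' @param models list with `c_bonds`, `n_ratio` and optionally `mp`
#'   calibration models, all tagged with the spectrum's excitation.
#' @param noise_sd noise level (counts), estimated when `NULL`.
#' @param ... passed to [intensity_ratios()].
#' @return object of class `lipid_quant`: list with `r1650_1440`,
#'   `r3003_1440`, `est_c_double_bonds`, `est_n_ratio`,
#'   `est_melting_point`, `excitation_nm`.
#' @export
quantify <- function(s, models, noise_sd = NULL, ...) {
  stopifnot(inherits(s, "raman_spectrum"))
  for (nm in intersect(c("c_bonds", "n_ratio", "mp"), names(models))) {
    m <- models[[nm]]
    if (!is.null(m) && m$excitation_nm != s$excitation_nm)
      stop(sprintf("calibration '%s' was fitted at %g nm but the spectrum is %g nm",
                   nm, m$excitation_nm, s$excitation_nm))
  }
  r <- intensity_ratios(s, noise_sd = noise_sd, ...)
  clip0 <- function(v, what) {
    if (is.finite(v) && v < 0) {
      warning(sprintf("negative %s estimate (%.3g) clipped to 0", what, v),
              call. = FALSE)
      0
    } else v
  }
  est_c <- clip0(predict_calibration(models$c_bonds, r$r1650_1440), "C=C")
  est_n <- clip0(predict_calibration(models$n_ratio, r$r1650_1440),
                 "N_C=C/N_CH2")
  est_mp <- if (!is.null(models$mp))
    tryCatch(invert_calibration(models$mp, r$r1650_1440),
             error = function(e) {
               warning(conditionMessage(e), call. = FALSE)
               NA_real_
             })
  else NA_real_
  structure(list(r1650_1440 = r$r1650_1440, r3003_1440 = r$r3003_1440,
                 est_c_double_bonds = est_c, est_n_ratio = est_n,
                 est_melting_point = est_mp,
                 excitation_nm = s$excitation_nm),
            class = "lipid_quant")
}

#' @export
print.lipid_quant <- function(x, ...) {
  cat(sprintf(paste0("<lipid_quant> %g nm: I1650/I1440 = %.3f, I3003/I1440 = %.3f\n",
                     "  C=C = %.2f, N_C=C/N_CH2 = %.3f, melting point = %s degC\n"),
              x$excitation_nm, x$r1650_1440, x$r3003_1440,
              x$est_c_double_bonds, x$est_n_ratio,
              if (is.na(x$est_melting_point)) "NA"
              else sprintf("%.1f", x$est_melting_point)))
  invisible(x)
}

#' Expected intensity ratio of a fatty-acid mixture
#'
#' Band areas add per mole of each component, so for a mixture given in
#' weight fractions the expected `I1650/I1440` ratio is the coupling
#' constant times the mole-weighted mean double-bond count over the
#' mole-weighted mean methylene count. The result always lies between the
#' pure-component ratios and varies monotonically with composition.
#'
#' @param components named numeric vector of weight fractions (names =
#'   fatty-acid codes), summing to 1, or a data frame with columns `code`
#'   and `weight`.
#' @param coupling generator coupling constant (7.3 at 532 nm).
#' @return dimensionless expected ratio.
#' @examples
#' mixture_ratio(c("C18:1" = 0.5, "C16:1" = 0.5))
#' @export
mixture_ratio <- function(components, coupling = 7.3) {
  if (is.data.frame(components))
    components <- stats::setNames(components$weight, components$code)
  counts <- mixture_counts(components)
  coupling * counts$n_double_bonds / counts$n_ch2
}

#' Classify single cells by lipid saturation
#'
#' Labels each cell by its estimated number of C=C bonds per fatty-acid
#' residue: `<= low` is "saturated-dominant", `>= high` is
#' "monounsaturated-dominant", anything between is "mixed". The default
#' thresholds 0.35 / 0.65 are midpoints between the saturated (0),
#' mixed (~0.5) and monounsaturated (~1) archetypes.
#'
#' @param quants list of [quantify()] results, or a numeric vector of
#'   `est_c_double_bonds` values.
#' @param thresholds numeric `c(low, high)`.
#' @return list with `labels` (character vector) and `counts` (named
#'   integer table over the three classes).
#' @export
classify_population <- function(quants, thresholds = c(0.35, 0.65)) {
  if (length(quants) < 1) stop("need at least one cell")
  est <- if (is.numeric(quants)) quants
  else vapply(quants, `[[`, 0, "est_c_double_bonds")
  classes <- c("saturated-dominant", "mixed", "monounsaturated-dominant")
  labels <- ifelse(est <= thresholds[1], classes[1],
                   ifelse(est >= thresholds[2], classes[3], classes[2]))
  counts <- table(factor(labels, levels = classes))
  list(labels = labels, counts = counts,
       n_occupied = sum(counts > 0))
}
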