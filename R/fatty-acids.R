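#' Fatty-acid standards: structural arithmetic and registry
#'
#' A fatty acid is described by the usual shorthand `C<carbons>:<double
#' bonds>` (e.g. `"C18:1"` for oleic acid). For straight-chain,
#' methylene-interrupted free fatty acids the number of aliphatic -CH2-
#' groups follows from the chain length and the number of C=C bonds:
#' the carboxyl carbon and the terminal methyl carbon are not methylenes,
#' and every *cis* double bond converts two methylenes into =CH- units,
#' so `n_ch2 = n_carbons - 2 - 2 * n_double_bonds`.
#'
#' @param code shorthand such as `"C18:1"`.
#' @param melting_point melting point in degrees Celsius.
#' @param name optional trivial name (e.g. `"oleic"`).
#' @return an object of class `fatty_acid`: a list with fields `name`,
#'   `code`, `n_carbons`, `n_double_bonds`, `melting_point`, and the derived
#'   `n_ch2` and `molecular_weight` (g/mol, free acid).
#' @examples
#' fa <- parse_fatty_acid("C18:1", melting_point = 13.4)
#' fa$n_ch2            # 14
#' unsaturation_ratio(fa)  # 1/14
#' @export
parse_fatty_acid <- function(code, melting_point = NA_real_, name = NULL) {
  if (length(code) != 1L || !is.character(code) ||
      !grepl("^C[0-9]+:[0-9]+$", code)) {
    abort_format(sprintf("malformed fatty-acid code '%s' (expected e.g. 'C18:1')",
                         as.character(code)[1]))
  }
  parts <- as.integer(strsplit(sub("^C", "", code), ":", fixed = TRUE)[[1]])
  n_carbons <- parts[1]
  n_double_bonds <- parts[2]
  if (n_carbons < 4)
    stop("fatty-acid chain must have at least 4 carbons, got ", n_carbons)
  if (n_double_bonds > (n_carbons - 2) / 2)
    stop(sprintf("%s: %d double bonds exceed the structural maximum for a %d-carbon methylene-interrupted chain",
                 code, n_double_bonds, n_carbons))
  n_ch2 <- n_carbons - 2L - 2L * n_double_bonds
  mw <- 12.011 * n_carbons + 1.008 * (2 * n_carbons - 2 * n_double_bonds) + 31.998
  structure(list(
    name = name %||% code,
    code = code,
    n_carbons = n_carbons,
    n_double_bonds = n_double_bonds,
    melting_point = melting_point,
    n_ch2 = n_ch2,
    molecular_weight = mw
  ), class = "fatty_acid")
}

#' @export
print.fatty_acid <- function(x, ...) {
  cat(sprintf("<fatty_acid> %s (%s): %d C, %d C=C, %d CH2, MW %.2f g/mol, mp %s degC\n",
              x$name, x$code, x$n_carbons, x$n_double_bonds, x$n_ch2,
              x$molecular_weight,
              if (is.na(x$melting_point)) "NA" else format(x$melting_point)))
  invisible(x)
}

#' Chain-normalized unsaturation of a fatty acid
#'
#' The number of C=C bonds per aliphatic methylene group,
#' `n_double_bonds / n_ch2`. This is the quantity the C=C-stretch to
#' CH2-bend intensity ratio is proportional to.
#'
#' @param fa a `fatty_acid`.
#' @return dimensionless ratio.
#' @export
unsaturation_ratio <- function(fa) {
  stopifnot(inherits(fa, "fatty_acid"))
  if (fa$n_ch2 == 0)
    stop(fa$code, ": unsaturation ratio undefined, chain has no CH2 groups")
  fa$n_double_bonds / fa$n_ch2
}

# melting points (degC) from standard chemistry references
.registry_table <- data.frame(
  code = c("C22:6", "C20:5", "C20:4", "C18:3", "C18:2", "C18:1",
           "C16:1", "C18:0", "C16:0", "C14:0", "C12:0"),
  name = c("docosahexaenoic", "eicosapentaenoic", "arachidonic",
           "alpha-linolenic", "linoleic", "oleic", "palmitoleic",
           "stearic", "palmitic", "myristic", "lauric"),
  melting_point = c(-44.0, -53.5, -49.5, -11.3, -6.9, 13.4,
                    -0.1, 69.3, 62.9, 54.2, 43.8),
  stringsAsFactors = FALSE
)

#' Default calibration panel of fatty-acid standards
#'
#' Eleven even-numbered fatty acids commonly found in microalgal lipid
#' extracts, spanning 0 to 6 C=C bonds, sorted by decreasing unsaturation
#' (ties broken by decreasing chain length). Melting points are literature
#' values; pass your own table to override.
#'
#' @param table optional replacement data frame with columns `code` and
#'   `melting_point` (and optionally `name`), e.g. from
#'   [read_registry()].
#' @return list of [fatty_acid][parse_fatty_acid] objects.
#' @export
standard_registry <- function(table = NULL) {
  tab <- table %||% .registry_table
  if (!all(c("code", "melting_point") %in% names(tab)))
    abort_format("registry table needs columns 'code' and 'melting_point'")
  fas <- lapply(seq_len(nrow(tab)), function(i) {
    parse_fatty_acid(tab$code[i], tab$melting_point[i],
                     name = if ("name" %in% names(tab)) tab$name[i] else NULL)
  })
  ord <- order(-vapply(fas, `[[`, 0L, "n_double_bonds"),
               -vapply(fas, `[[`, 0L, "n_carbons"))
  fas[ord]
}

#' Read / write a fatty-acid registry table
#'
#' Plain delimited text with columns `code` and `melting_point_C`
#' (optionally `name`); lines starting with `#` are comments.
#'
#' @param path file path.
#' @return `read_registry()`: a data frame suitable for
#'   [standard_registry()]; `write_registry()`: `path`, invisibly.
#' @export
read_registry <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!all(c("code", "melting_point_C") %in% names(tab)))
    abort_format(sprintf("%s: expected columns 'code' and 'melting_point_C'", path))
  names(tab)[names(tab) == "melting_point_C"] <- "melting_point"
  tab
}

#' @param registry list of `fatty_acid` objects (e.g. [standard_registry()]).
#' @rdname read_registry
#' @export
write_registry <- function(registry, path) {
  tab <- data.frame(
    code = vapply(registry, `[[`, "", "code"),
    name = vapply(registry, `[[`, "", "name"),
    melting_point_C = vapply(registry, `[[`, 0, "melting_point")
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# fatty-acid standard registry", con)
  utils::write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# mole-weighted effective methylene / double-bond counts of a lipid mixture.
# `lipids` is a named numeric vector of weight fractions, names are codes
# resolvable in the registry (or a list of fatty_acid objects with a
# `weights` attribute). Returns list(n_ch2, n_double_bonds, components).
mixture_counts <- function(lipids, registry = standard_registry()) {
  if (is.null(names(lipids)) || any(!nzchar(names(lipids))))
    stop("lipid mixture must be a named numeric vector of weight fractions")
  if (any(lipids < 0)) stop("lipid weight fractions must be >= 0")
  if (abs(sum(lipids) - 1) > 1e-6)
    stop("lipid weight fractions must sum to 1 (got ", format(sum(lipids)), ")")
  lookup <- stats::setNames(registry, vapply(registry, `[[`, "", "code"))
  fas <- lapply(names(lipids), function(code) {
    lookup[[code]] %||% parse_fatty_acid(code)
  })
  moles <- lipids / vapply(fas, `[[`, 0, "molecular_weight")
  moles <- moles / sum(moles)
  list(
    n_ch2 = sum(moles * vapply(fas, `[[`, 0L, "n_ch2")),
    n_double_bonds = sum(moles * vapply(fas, `[[`, 0L, "n_double_bonds")),
    mole_fractions = stats::setNames(as.numeric(moles), names(lipids))
  )
}
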