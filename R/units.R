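#' Physical constants and unit conversions
#'
#' All internal computation is in SI units (m, s, kg, mol, K). The public
#' constructors accept the units customary in the digestion literature
#' (mPa s, mM, mM/min, minutes or hours for emptying half-times) and convert
#' on ingest; these helpers centralise the conversions.
#'
#' @name units
#' @keywords internal
NULL

#' Boltzmann constant (CODATA 2018), J/K.
#' @export
BOLTZMANN_K <- 1.380649e-23

# mM -> mol/L
.mM_to_molar <- function(x) x * 1e-3

# mM/min -> mol L^-1 s^-1
.mM_per_min_to_molar_per_s <- function(x) x * 1e-3 / 60

# mol/m^3 <-> mol/L
.molar_to_mol_m3 <- function(x) x * 1000

#' Parse a unit-bearing quantity string
#'
#' Accepts either a bare number (taken to be in `default_unit`) or a string
#' such as `"5 mPa.s"`, `"9 mM/min"`, `"30 min"`, `"1 h"`. Only the units
#' used in this model family are recognised; anything else is an error, so
#' configuration typos fail loudly rather than silently changing scale.
#'
#' @param x number or string.
#' @param kind one of `"viscosity"`, `"concentration"`, `"rate"`, `"time"`,
#'   `"mass"`, `"length"`.
#' @param field field name used in error messages.
#' @return numeric value in SI units (Pa s, mol/L, mol L^-1 s^-1, s, g, m).
#' @export
parse_quantity <- function(x, kind, field = deparse(substitute(x))) {
  units <- switch(kind,
    viscosity = c("Pa.s" = 1, "Pa s" = 1, "mPa.s" = 1e-3, "mPa s" = 1e-3),
    concentration = c("mM" = 1e-3, "M" = 1, "mol/L" = 1),
    rate = c("mM/min" = 1e-3 / 60, "mM/s" = 1e-3, "M/s" = 1),
    time = c("s" = 1, "sec" = 1, "min" = 60, "h" = 3600, "hr" = 3600),
    mass = c("g" = 1, "kg" = 1000),
    length = c("m" = 1, "cm" = 1e-2, "mm" = 1e-3, "nm" = 1e-9),
    stop("unknown quantity kind: ", kind)
  )
  if (is.numeric(x)) {
    return(as.numeric(x))
  }
  if (!is.character(x) || length(x) != 1L) {
    stop(sprintf("field '%s': expected a number or a unit string", field))
  }
  m <- regmatches(x, regexec("^\\s*([-+0-9.eE]+)\\s*(.*?)\\s*$", x))[[1]]
  val <- suppressWarnings(as.numeric(m[2]))
  unit <- m[3]
  if (is.na(val)) {
    stop(sprintf("field '%s': cannot parse numeric value from '%s'", field, x))
  }
  if (unit == "") {
    return(val)
  }
  if (!unit %in% names(units)) {
    stop(sprintf(
      "field '%s': unit '%s' not recognised for %s (accepted: %s)",
      field, unit, kind, paste(names(units), collapse = ", ")
    ))
  }
  val * units[[unit]]
}

# internal: stop with the offending field named, used by all validators
.check_positive <- function(x, field, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (strict && x <= 0) || (!strict && x < 0)) {
    stop(sprintf(
      "field '%s' must be a %s real number (got %s)",
      field, if (strict) "strictly positive" else "non-negative",
      paste(format(x), collapse = ",")
    ), call. = FALSE)
  }
  invisible(x)
}
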