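#' Parse a quantity string with explicit units into SI
#'
#' Configuration files carry every physical quantity as a string with an
#' explicit unit (`"0.08 ul/s"`, `"135 MHz"`, `"25 mPa s"`). This parser
#' converts them to SI base quantities (m, s, Hz, Pa, kg m^-3, m^3 s^-1,
#' particles m^-3, ...) so that no silent unit mistake can enter the physics.
#'
#' @param x character vector of `"<number> <unit>"` strings, or bare numbers
#'   (returned unchanged with a warning unless `unit` supplies a default).
#' @param expect optional dimension name (e.g. `"length"`); parsing errors if
#'   the unit found belongs to a different dimension.
#' @return numeric vector in SI units.
#' @examples
#' parse_quantity("0.08 ul/s")   # 8e-11 m^3/s
#' parse_quantity("2.25 um")     # 2.25e-06 m
#' parse_quantity("135 MHz")     # 1.35e+08 Hz
#' @export
parse_quantity <- function(x, expect = NULL) {
  vapply(x, parse_quantity_one, numeric(1), expect = expect, USE.NAMES = FALSE)
}

# unit -> list(factor to SI, dimension)
.unit_table <- list(
  "m"        = list(1,      "length"),
  "cm"       = list(1e-2,   "length"),
  "mm"       = list(1e-3,   "length"),
  "um"       = list(1e-6,   "length"),
  "nm"       = list(1e-9,   "length"),
  "m2"       = list(1,      "area"),
  "um2"      = list(1e-12,  "area"),
  "m3"       = list(1,      "volume"),
  "l"        = list(1e-3,   "volume"),
  "ml"       = list(1e-6,   "volume"),
  "ul"       = list(1e-9,   "volume"),
  "nl"       = list(1e-12,  "volume"),
  "s"        = list(1,      "time"),
  "ms"       = list(1e-3,   "time"),
  "us"       = list(1e-6,   "time"),
  "min"      = list(60,     "time"),
  "h"        = list(3600,   "time"),
  "Hz"       = list(1,      "frequency"),
  "kHz"      = list(1e3,    "frequency"),
  "MHz"      = list(1e6,    "frequency"),
  "Pa"       = list(1,      "pressure"),
  "kPa"      = list(1e3,    "pressure"),
  "MPa"      = list(1e6,    "pressure"),
  "1/Pa"     = list(1,      "compressibility"),
  "Pa s"     = list(1,      "viscosity"),
  "mPa s"    = list(1e-3,   "viscosity"),
  "kg/m3"    = list(1,      "density"),
  "g/ml"     = list(1e3,    "density"),
  "J/m3"     = list(1,      "energy_density"),
  "m/s"      = list(1,      "speed"),
  "cm/s"     = list(1e-2,   "speed"),
  "mm/s"     = list(1e-3,   "speed"),
  "m3/s"     = list(1,      "flow"),
  "ml/s"     = list(1e-6,   "flow"),
  "ul/s"     = list(1e-9,   "flow"),
  "nl/s"     = list(1e-12,  "flow"),
  "1/m3"     = list(1,      "concentration"),
  "1/ml"     = list(1e6,    "concentration"),
  "cells/ml" = list(1e6,    "concentration"),
  "1/s"      = list(1,      "rate"),
  "N"        = list(1,      "force"),
  "W"        = list(1,      "power")
)

parse_quantity_one <- function(x, expect = NULL) {
  if (is.numeric(x)) return(x)
  x <- trimws(x)
  m <- regmatches(x, regexec("^([-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?)\\s*(.*)$", x))[[1]]
  if (length(m) == 0) {
    rlang::abort(sprintf("cannot parse quantity '%s'", x), class = "acoustosort_config_error")
  }
  value <- as.numeric(m[2])
  unit <- trimws(m[3])
  entry <- if (unit == "") list(1, "dimensionless") else .unit_table[[unit]]
  if (is.null(entry)) {
    rlang::abort(sprintf("unknown unit '%s' in quantity '%s'", unit, x),
                 class = "acoustosort_config_error")
  }
  if (!is.null(expect) && !identical(entry[[2]], expect)) {
    rlang::abort(sprintf("quantity '%s' has dimension '%s', expected '%s'",
                         x, entry[[2]], expect),
                 class = "acoustosort_config_error")
  }
  value * entry[[1]]
}

#' Format an SI value in a chosen unit
#'
#' Inverse of [parse_quantity()]; division by the exact conversion factor
#' keeps round trips lossless to double precision.
#'
#' @param x numeric SI value.
#' @param unit target unit string known to the unit table.
#' @return numeric value expressed in `unit`.
#' @export
si_to_unit <- function(x, unit) {
  entry <- .unit_table[[unit]]
  if (is.null(entry)) {
    rlang::abort(sprintf("unknown unit '%s'", unit), class = "acoustosort_config_error")
  }
  x / entry[[1]]
}
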