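# Canonical internal units: concentration µM, amount µmol, time min, volume L,
# flow L/min, clearance L/min, rate 1/min, mass mg. All config inputs carry
# explicit unit strings and are converted once at load.

.unit_table <- list(
  concentration = c("M" = 1e6, "mM" = 1e3, "uM" = 1, "µM" = 1, "umol/L" = 1,
                    "µmol/L" = 1, "nM" = 1e-3, "pM" = 1e-6),
  amount        = c("mol" = 1e6, "mmol" = 1e3, "umol" = 1, "µmol" = 1,
                    "nmol" = 1e-3),
  time          = c("min" = 1, "s" = 1 / 60, "h" = 60, "d" = 1440, "day" = 1440),
  volume        = c("L" = 1, "l" = 1, "mL" = 1e-3, "ml" = 1e-3),
  flow          = c("L/min" = 1, "L/h" = 1 / 60, "mL/min" = 1e-3, "ml/min" = 1e-3,
                    "L/hr" = 1 / 60),
  clearance     = c("L/min" = 1, "L/h" = 1 / 60, "mL/min" = 1e-3, "ml/min" = 1e-3,
                    "L/hr" = 1 / 60),
  rate          = c("1/min" = 1, "1/h" = 1 / 60, "1/s" = 60, "min-1" = 1,
                    "h-1" = 1 / 60),
  mass          = c("mg" = 1, "g" = 1e3, "ug" = 1e-3, "µg" = 1e-3, "kg" = 1e6),
  dimensionless = c("1" = 1, "-" = 1)
)

#' Parse a quantity with an explicit unit into canonical internal units
#'
#' Quantities in configuration files are written as `"value unit"` strings
#' (e.g. `"3.6 nM"`, `"1.5 L/h"`) or bare numbers already in canonical units.
#' Canonical units are micromolar (concentration), micromole (amount), minute
#' (time), litre (volume), L/min (flow and clearance) and 1/min (first-order
#' rate).
#'
#' @param x A `"value unit"` string or a bare number.
#' @param dimension One of "concentration", "amount", "time", "volume",
#'   "flow", "clearance", "rate", "mass", "dimensionless".
#' @param field Field name used in error messages.
#' @return Numeric scalar in canonical units.
#' @examples
#' parse_quantity("3.6 nM", "concentration")   # 0.0036
#' parse_quantity("1 h", "time")               # 60
#' @export
parse_quantity <- function(x, dimension, field = deparse(substitute(x))) {
  units <- .unit_table[[dimension]]
  if (is.null(units)) stop("unknown dimension: ", dimension)
  if (is.numeric(x)) {
    if (length(x) != 1L || !is.finite(x))
      stop("field '", field, "': expected a finite scalar quantity")
    return(as.numeric(x))
  }
  if (!is.character(x) || length(x) != 1L)
    stop("field '", field, "': expected a number or a 'value unit' string")
  m <- regmatches(x, regexec("^\\s*([-+0-9.eE]+)\\s*(\\S*)\\s*$", x))[[1]]
  if (length(m) == 0L || is.na(suppressWarnings(val <- as.numeric(m[2]))))
    stop("field '", field, "': cannot parse quantity '", x, "'")
  unit <- m[3]
  if (unit == "") return(val)   # bare number string: already canonical
  if (!unit %in% names(units))
    stop("field '", field, "': unit '", unit, "' is not a ", dimension,
         " unit; allowed: ", paste(setdiff(names(units), ""), collapse = ", "))
  val * units[[unit]]
}

# format a canonical value back to a config string (canonical unit label)
.canonical_label <- c(concentration = "uM", amount = "umol", time = "min",
                      volume = "L", flow = "L/min", clearance = "L/min",
                      rate = "1/min", mass = "mg", dimensionless = "")

format_quantity <- function(value, dimension) {
  lab <- .canonical_label[[dimension]]
  if (lab == "") as.character(value) else paste(value, lab)
}
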