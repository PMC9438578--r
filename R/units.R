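#' Unit conversions
#'
#' Clinical inputs arrive in mmHg and millimetres; all model arithmetic is
#' done in SI (Pa, m). `convert_pressure()` converts a pressure to pascal,
#' `pressure_as()` converts a pascal value back to a requested unit.
#'
#' @param value numeric vector of pressures.
#' @param unit one of `"mmHg"`, `"kPa"`, `"Pa"`.
#' @return numeric vector in Pa (`convert_pressure`) or in `unit`
#'   (`pressure_as`).
#' @examples
#' convert_pressure(120, "mmHg")     # 15998.64 Pa
#' pressure_as(convert_pressure(1, "mmHg"), "mmHg")
#' @export
convert_pressure <- function(value, unit = c("mmHg", "kPa", "Pa")) {
  if (!is.numeric(value) || anyNA(value) || any(!is.finite(value)))
    abort_config("pressure 'value' must be finite numeric")
  if (length(unit) != 1L || !unit %in% c("mmHg", "kPa", "Pa"))
    abort_config(sprintf("unknown pressure unit '%s' (use mmHg, kPa or Pa)",
                         paste(unit, collapse = ",")))
  switch(unit,
         mmHg = value * MMHG_PA,
         kPa  = value * 1000,
         Pa   = value)
}

#' @rdname convert_pressure
#' @param value_pa numeric vector in Pa.
#' @export
pressure_as <- function(value_pa, unit = c("mmHg", "kPa", "Pa")) {
  unit <- match.arg(unit)
  switch(unit,
         mmHg = value_pa / MMHG_PA,
         kPa  = value_pa / 1000,
         Pa   = value_pa)
}

# 1 mmHg in Pa
MMHG_PA <- 133.322

convert_length <- function(value, unit = c("mm", "m", "cm")) {
  if (length(unit) != 1L || !unit %in% c("mm", "m", "cm"))
    abort_config(sprintf("unknown length unit '%s'", paste(unit, collapse = ",")))
  switch(unit, mm = value / 1000, cm = value / 100, m = value)
}
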