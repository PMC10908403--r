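#' Convert a pressure value between units
#'
#' The package works in SI units internally (pressure in Pa); mmHg and kPa
#' appear only at input/output boundaries.  The conversion is exact and
#' affine-free (all three units share a zero): 1 mmHg = 133.322 Pa.
#'
#' @param value numeric vector of pressure values.
#' @param from,to unit labels, one of `"Pa"`, `"kPa"`, `"mmHg"`.
#' @return numeric vector in the target unit.
#' @examples
#' convert_pressure(40, "mmHg", "Pa")   # 5332.88
#' convert_pressure(1, "kPa", "Pa")     # 1000
#' @export
convert_pressure <- function(value, from, to) {
  to_pa <- c(Pa = 1, kPa = 1000, mmHg = 133.322)
  if (!from %in% names(to_pa)) stop("unknown pressure unit: ", from)
  if (!to %in% names(to_pa)) stop("unknown pressure unit: ", to)
  value * to_pa[[from]] / to_pa[[to]]
}

#' @rdname convert_pressure
#' @export
MMHG_PA <- 133.322
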