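#' Olufsen wall law: stiffness-thickness product
#'
#' The empirical wall law links the product of effective Young's modulus `E`
#' and wall thickness `h` to the luminal radius `r`:
#' `Eh / r = k1 * exp(k2 * r) + k3`, with `k1` describing the stiffness of
#' smaller arteries, `k2` the radius at which stiffness transitions (usually
#' negative, 1/m) and `k3` the stiffness of larger arteries.
#'
#' @param r luminal radius in m (> 0); vectorised.
#' @param k1,k2,k3 wall-law constants (Pa, 1/m, Pa).
#' @return `Eh` in Pa*m: `r * (k1 * exp(k2 * r) + k3)`.
#' @examples
#' eh_product(0.01, k1 = 0, k2 = 0, k3 = 4e5)  # 4000 Pa m
#' @export
eh_product <- function(r, k1, k2, k3) {
  if (any(r <= 0)) stop("radius must be positive")
  r * (k1 * exp(k2 * r) + k3)
}

#' Effective Young's modulus of one arterial segment
#'
#' Evaluates the wall law at the segment's mean radius (average of inlet and
#' outlet radii) and divides out the wall thickness using the segment's
#' thickness-to-radius ratio: `E = Eh / (h_over_r * r_mean)`.
#'
#' @param seg an [arterial_segment].
#' @return Young's modulus in Pa.
#' @export
segment_young_modulus <- function(seg) {
  stopifnot(inherits(seg, "arterial_segment"))
  r <- (seg$r_in + seg$r_out) / 2
  eh_product(r, seg$k1, seg$k2, seg$k3) / (seg$h_over_r * r)
}

#' Length-weighted aortic Young's modulus
#'
#' The reference aortic stiffness: the mean of the per-segment Young's moduli
#' weighted by segment length, `E_Ao = sum_j (L_j / L_Ao) E_j` with
#' `L_Ao = sum_j L_j`.
#'
#' @param path non-empty list of [arterial_segment] along the aorta.
#' @return `E_Ao` in Pa.
#' @export
aortic_young_modulus <- function(path) {
  if (!length(path)) stop("aortic path is empty")
  L <- vapply(path, function(s) s$length, 0)
  E <- vapply(path, segment_young_modulus, 0)
  sum(L * E) / sum(L)
}

#' Theoretical aortic-root pulse wave velocity
#'
#' The thin-wall elastic (Bramwell-Hill / Moens-Korteweg) wave speed at a
#' segment's mean radius: `pwv = sqrt(2 Eh / (3 rho r))` with `Eh` from the
#' Olufsen wall law.  With `h_over_r` fixed this reduces to
#' `sqrt(2 h_over_r E / (3 rho))` (= `sqrt(0.1 E / rho)` at `h_over_r` 0.15).
#'
#' @param seg an [arterial_segment] (the aortic-root segment for the
#'   reference value).
#' @param rho blood density in kg/m^3.
#' @return wave speed in m/s.
#' @export
theoretical_ao_pwv <- function(seg, rho = 1060) {
  stopifnot(rho > 0)
  r <- (seg$r_in + seg$r_out) / 2
  sqrt(2 * eh_product(r, seg$k1, seg$k2, seg$k3) / (3 * rho * r))
}

# local wave speed for each segment of a path (m/s)
segment_wave_speeds <- function(path, rho) {
  vapply(path, theoretical_ao_pwv, 0, rho = rho)
}
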