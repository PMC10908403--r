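PW_SITES <- c("aortic_root", "carotid", "brachial", "radial", "digital",
              "femoral", "ankle", "desc_aorta")
PW_MODALITIES <- c("pressure", "flow_velocity", "area", "ppg")

#' Single-beat pulse wave
#'
#' A uniformly sampled single cardiac cycle of a pressure, flow-velocity,
#' luminal-area or photoplethysmogram (PPG) signal at a named arterial site.
#' Units are SI: pressure in Pa, velocity in m/s, area in m^2; PPG is
#' dimensionless.  The first sample lies at or before the pulse foot and the
#' last at end of diastole; all operations in the package act on one
#' pre-segmented beat.
#'
#' @param samples numeric vector, length >= 3, all finite.
#' @param fs sampling frequency in Hz (> 0).
#' @param site arterial site label, one of
#'   `r paste0('\x60', PW_SITES, '\x60', collapse = ", ")`.
#' @param modality signal modality, one of `pressure`, `flow_velocity`,
#'   `area`, `ppg`.
#' @return an object of class `pulse_wave`: a list with elements `samples`,
#'   `fs`, `site`, `modality`.
#' @examples
#' pw <- pulse_wave(sin(seq(0, 2 * pi, length.out = 100))^2, fs = 100,
#'                  site = "carotid", modality = "pressure")
#' pw
#' @export
pulse_wave <- function(samples, fs, site, modality) {
  samples <- as.numeric(samples)
  if (length(samples) < 3L) stop("pulse_wave needs at least 3 samples")
  if (!all(is.finite(samples))) stop("pulse_wave samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  site <- match.arg(site, PW_SITES)
  modality <- match.arg(modality, PW_MODALITIES)
  structure(list(samples = samples, fs = fs, site = site,
                 modality = modality),
            class = "pulse_wave")
}

#' @export
print.pulse_wave <- function(x, ...) {
  cat(sprintf("<pulse_wave> %s %s: %d samples @ %g Hz (%.3f s), range [%g, %g]\n",
              x$site, x$modality, length(x$samples), x$fs,
              length(x$samples) / x$fs, min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.pulse_wave <- function(x) length(x$samples)

#' @export
plot.pulse_wave <- function(x, ...) {
  plot(pw_time(x), x$samples, type = "l",
       xlab = "time [s]", ylab = x$modality,
       main = sprintf("%s %s", x$site, x$modality), ...)
  invisible(x)
}

# time axis of a beat, starting at 0
pw_time <- function(wave) (seq_along(wave$samples) - 1) / wave$fs

# beat period in seconds
pw_period <- function(wave) length(wave$samples) / wave$fs

# replace samples, keeping metadata
pw_replace <- function(wave, samples) {
  wave$samples <- as.numeric(samples)
  wave
}

is_pulse_wave <- function(x) inherits(x, "pulse_wave")

#' Arterial segment geometry and wall-law constants
#'
#' One segment of the arterial tree: its length, inlet/outlet luminal radii
#' and the Olufsen wall-law constants `k1` (stiffness of smaller arteries,
#' Pa), `k2` (transition with radius, 1/m, usually negative) and `k3`
#' (stiffness of larger arteries, Pa), plus the wall thickness-to-radius
#' ratio `h_over_r` (default 0.15).
#'
#' @param length segment length in m (> 0).
#' @param r_in,r_out inlet and outlet luminal radii in m (> 0).
#' @param k1,k2,k3 wall-law constants (Pa, 1/m, Pa).
#' @param h_over_r wall thickness-to-radius ratio in (0, 1).
#' @return an object of class `arterial_segment`.
#' @export
arterial_segment <- function(length, r_in, r_out, k1, k2, k3,
                             h_over_r = 0.15) {
  stopifnot(length > 0, r_in > 0, r_out > 0,
            h_over_r > 0, h_over_r < 1,
            is.finite(k1), is.finite(k2), is.finite(k3))
  structure(list(length = length, r_in = r_in, r_out = r_out,
                 k1 = k1, k2 = k2, k3 = k3, h_over_r = h_over_r),
            class = "arterial_segment")
}

#' @export
print.arterial_segment <- function(x, ...) {
  cat(sprintf(
    "<arterial_segment> L=%.3f m, r=[%.4f -> %.4f] m, k=(%.3g Pa, %.3g 1/m, %.3g Pa), h/r=%.2f\n",
    x$length, x$r_in, x$r_out, x$k1, x$k2, x$k3, x$h_over_r))
  invisible(x)
}

#' Virtual subject
#'
#' A subject record holding age, height, blood density, the ordered aortic
#' path (10 arterial segments), per-site-pair path lengths used by the
#' transit-time indices, and the set of single-beat waveforms keyed by
#' `site.modality`.
#'
#' @param id subject identifier (character).
#' @param age age in years.
#' @param height height in m.
#' @param rho blood density in kg/m^3 (default 1060).
#' @param aortic_path list of [arterial_segment] from root to distal aorta.
#' @param path_lengths named numeric vector of path distances in m; names are
#'   site-pair labels (`ao`, `cf`, `ba`, `cb`, `cr`, `ft`, `ha`).
#' @param waves named list of [pulse_wave] objects; names `"site.modality"`.
#' @return an object of class `virtual_subject`.
#' @export
virtual_subject <- function(id, age, height, rho = 1060,
                            aortic_path, path_lengths, waves) {
  stopifnot(length(aortic_path) >= 1,
            all(vapply(aortic_path, inherits, TRUE, "arterial_segment")),
            all(path_lengths > 0),
            height > 0, rho > 0)
  if (length(waves)) {
    stopifnot(all(vapply(waves, is_pulse_wave, TRUE)))
    fss <- vapply(waves, function(w) w$fs, 0)
    if (diff(range(fss)) != 0)
      stop("all waves of one subject must share the same fs")
  }
  structure(list(id = as.character(id), age = age, height = height,
                 rho = rho, aortic_path = aortic_path,
                 path_lengths = path_lengths, waves = waves),
            class = "virtual_subject")
}

#' @export
print.virtual_subject <- function(x, ...) {
  cat(sprintf("<virtual_subject> %s: age %g yr, height %.2f m, %d aortic segments, %d waves\n",
              x$id, x$age, x$height, length(x$aortic_path), length(x$waves)))
  invisible(x)
}

#' Fetch one waveform of a subject
#'
#' @param subject a [virtual_subject].
#' @param site,modality wave key (see [pulse_wave]).
#' @return the [pulse_wave], or `NULL` when the subject lacks that signal.
#' @export
subject_wave <- function(subject, site, modality) {
  subject$waves[[paste(site, modality, sep = ".")]]
}

#' Names of the 19 vascular aging indices
#'
#' @return character vector of the index names used throughout the package.
#' @export
index_names <- function() {
  c("aoPWV", "cfPWV", "baPWV", "cbPWV", "crPWV", "ftPWV",
    "cPP", "bPP", "AP", "AIx", "Pb_amp", "RM",
    "CAVI", "DC",
    "RI_ppg", "SI_ppg", "AGI", "AIx_ppg", "d_over_a")
}

#' Construct an index panel
#'
#' A named numeric vector over the 19 indices with an attached record of why
#' any value is missing.  Missing indices are `NA`, never silently zero.
#'
#' @param values named numeric vector; names must be a subset of
#'   [index_names()].  Unnamed indices are `NA`.
#' @param missing named character vector of reasons for absent indices.
#' @return object of class `index_panel` (a named numeric vector with a
#'   `missing` attribute).
#' @export
index_panel <- function(values = numeric(), missing = character()) {
  out <- stats::setNames(rep(NA_real_, length(index_names())), index_names())
  if (length(values)) {
    bad <- setdiff(names(values), index_names())
    if (length(bad)) stop("unknown index name(s): ", paste(bad, collapse = ", "))
    out[names(values)] <- values
  }
  structure(out, missing = missing, class = "index_panel")
}

#' @export
print.index_panel <- function(x, ...) {
  cat("<index_panel>\n")
  v <- unclass(x)
  attributes(v) <- list(names = names(v))
  print(v)
  miss <- attr(x, "missing")
  if (length(miss))
    cat("missing:", paste0(names(miss), " (", miss, ")", collapse = "; "), "\n")
  invisible(x)
}

#' @export
as.data.frame.index_panel <- function(x, ...) {
  as.data.frame(as.list(unclass(x)), ...)
}
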