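#' Add white Gaussian noise at a prescribed signal-to-noise ratio
#'
#' Adds zero-mean white Gaussian noise whose variance is set from the
#' signal's average power: `var = mean(x^2) / 10^(snr_db / 10)`, so that the
#' realized SNR (linear power ratio, expressed in dB) matches `snr_db` in
#' expectation.  Deterministic for a fixed seed; each call draws its noise
#' independently of the caller's RNG state.
#'
#' @param wave a [pulse_wave].
#' @param snr_db target signal-to-noise ratio in decibels.
#' @param seed integer seed for the noise draw.
#' @return a [pulse_wave] with the same length, fs and metadata.
#' @export
add_white_noise <- function(wave, snr_db, seed) {
  stopifnot(is.finite(snr_db))
  x <- wave$samples
  sigma <- sqrt(mean(x^2) / 10^(snr_db / 10))
  noise <- with_seed(seed, rnorm(length(x), 0, sigma))
  pw_replace(wave, x + noise)
}

#' Zero-phase band-pass filter for pulse waves
#'
#' Removes frequency content above 35 Hz and below 0.0665 Hz.  The single
#' beat is tiled periodically (at least `tile_s` seconds) to make the
#' sub-0.1 Hz edge resolvable and to push filter transients away from the
#' analysed beat, filtered forward-backward (zero phase, so foot-to-foot
#' timings are preserved) with cascaded order-4 Butterworth high-pass and
#' low-pass sections, and the central beat is extracted.  The input's mean
#' is removed before filtering and restored afterwards so absolute pressure
#' levels survive the high-pass stage.
#'
#' @param wave a [pulse_wave] with `fs > 70` Hz.
#' @param low,high band edges in Hz.
#' @param tile_s minimum tiled duration in seconds.
#' @return a filtered [pulse_wave] of the same length.
#' @export
bandpass_filter <- function(wave, low = 0.0665, high = 35, tile_s = 16) {
  fs <- wave$fs
  if (fs <= 2 * high) stop("fs must exceed twice the upper band edge")
  x <- wave$samples
  n <- length(x)
  mu <- mean(x)
  reps <- max(3L, ceiling(tile_s * fs / n))
  if (reps %% 2 == 0) reps <- reps + 1L
  tiled <- rep(x - mu, reps)
  hp <- signal::butter(4, low / (fs / 2), type = "high")
  lp <- signal::butter(4, high / (fs / 2), type = "low")
  f <- signal::filtfilt(lp, signal::filtfilt(hp, tiled))
  mid <- (reps %/% 2) * n
  out <- f[(mid + 1):(mid + n)]
  pw_replace(wave, out - mean(out) + mu)
}

#' Realized signal-to-noise ratio
#'
#' The linear SNR is the average power of the clean signal over the average
#' power of the noise actually present, reported in decibels:
#' `10 log10(mean(clean^2) / mean((noisy - clean)^2))`.
#'
#' @param clean,noisy [pulse_wave]s (or numeric vectors) of equal length.
#' @return SNR in dB; `Inf` (with a warning) when the signals are identical.
#' @export
realized_snr <- function(clean, noisy) {
  x <- if (is_pulse_wave(clean)) clean$samples else as.numeric(clean)
  y <- if (is_pulse_wave(noisy)) noisy$samples else as.numeric(noisy)
  if (length(x) != length(y)) stop("clean and noisy must have equal length")
  pn <- mean((y - x)^2)
  if (pn == 0) {
    warning("signals are identical; SNR is infinite")
    return(Inf)
  }
  10 * log10(mean(x^2) / pn)
}

# apply the noise + filter pipeline to every wave of a subject; snr_db = Inf
# leaves the subject untouched (clean signals are not filtered)
perturb_subject <- function(subject, snr_db, seed) {
  if (!is.finite(snr_db)) return(subject)
  waves <- subject$waves
  for (i in seq_along(waves)) {
    noisy <- add_white_noise(waves[[i]], snr_db, seed = seed + i)
    waves[[i]] <- bandpass_filter(noisy)
  }
  subject$waves <- waves
  subject
}
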