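# --- smoothing-differentiation helpers ------------------------------------
#
# Derivatives of sampled beats are noise-amplifying, so all derivatives are
# taken with a local-polynomial (Savitzky-Golay) smoothing differentiator:
# window ~50 ms, polynomial order 3 (order 5 when the 4th derivative is
# needed).  Beats are treated as periodic: the signal is padded circularly
# before filtering so detectors are exactly equivariant to circular shifts.

sg_window <- function(wave, ms = 50) {
  n <- length(wave$samples)
  w <- max(5L, round(wave$fs * ms / 1000))
  if (w %% 2 == 0) w <- w + 1L
  min(w, if (n %% 2 == 1) n else n - 1L)
}

# circular Savitzky-Golay derivative of order m (per second^m)
sg_deriv <- function(wave, m = 0, p = 3, ms = 50) {
  x <- wave$samples
  n <- length(x)
  w <- sg_window(wave, ms)
  if (p <= m) p <- m + 1
  if (w <= p) w <- p + (p %% 2) + 1
  pad <- min(n, w)
  xp <- c(x[(n - pad + 1):n], x, x[1:pad])
  d <- signal::sgolayfilt(xp, p = p, n = w, m = m, ts = 1 / wave$fs)
  d[(pad + 1):(pad + n)]
}

# indices of strict interior local maxima (plateau-tolerant via run centres)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer())
  # plateau-tolerant: operate on run-length compressed values
  r <- rle(x)
  v <- r$values
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- length(v)
  if (k < 3) return(integer())
  idx <- which(v[2:(k - 1)] > v[1:(k - 2)] & v[2:(k - 1)] > v[3:k]) + 1
  out <- floor((starts[idx] + ends[idx]) / 2)
  out
}

local_minima <- function(x) local_maxima(-x)

# topographic prominence of each local maximum: height above the higher of
# the bounding minima (walking out to the first higher point on each side)
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(m) {
    v <- x[m]
    left <- x[seq_len(m - 1)]
    hil <- which(left > v)
    lmin <- min(left[if (length(hil)) (max(hil) + 1):(m - 1) else seq_len(m - 1)])
    right <- x[(m + 1):length(x)]
    hir <- which(right > v)
    rmin <- min(right[seq_len(if (length(hir)) min(hir) - 1 else length(right))])
    v - max(lmin, rmin)
  }, 0)
}

# --- pulse foot ------------------------------------------------------------

#' Locate the foot of a pulse wave (intersecting-tangent method)
#'
#' The foot is the intersection of the horizontal line through the
#' pre-systolic minimum with the tangent to the waveform at its point of
#' maximum systolic upslope, giving sub-sample resolution.  The beat is
#' treated as periodic, so the result is equivariant to circular shifts.
#'
#' @param wave a [pulse_wave].
#' @return foot time in seconds (within `[0, period)`).
#' @export
pulse_foot <- function(wave) {
  y <- wave$samples
  n <- length(y)
  if (max(y) - min(y) <= 0)
    stop("non-positive maximum slope; no systolic upstroke")
  # p = 2 gives the local-linear-regression slope (quadratic terms do not
  # enter an odd derivative), which never overshoots the true slope at
  # piecewise-linear corners
  d1 <- sg_deriv(wave, m = 1, p = 2)
  i_ms <- which.max(d1)
  slope <- d1[i_ms]
  if (slope <= 0) stop("non-positive maximum slope; no systolic upstroke")
  # walk backwards (circularly) from the max-slope point to the local minimum
  j <- i_ms
  for (step in seq_len(n - 1L)) {
    jp <- if (j == 1L) n else j - 1L
    if (y[jp] >= y[j]) break
    j <- jp
  }
  y_min <- y[j]
  t_ms <- (i_ms - 1) / wave$fs
  foot <- t_ms - (y[i_ms] - y_min) / slope
  foot %% pw_period(wave)
}

# signed circular time difference a -> b wrapped into [0, period)
wrap_delay <- function(t_a, t_b, period) (t_b - t_a) %% period

# --- pressure inflections --------------------------------------------------

# shared shoulder search: returns list(pre=..., post=...) sample indices of
# the early/late systolic shoulder relative to the main peak, or NULL.
# Shoulders are located from the smoothed first derivative: a zero crossing
# or local minimum of d1 before the peak (early shoulder), a local maximum
# of d1 after the peak (late shoulder); candidates too close to the peak or
# outside the systolic window are discarded.
find_shoulders <- function(wave, i_ft, i_pk) {
  y <- wave$samples
  n <- length(y)
  fs <- wave$fs
  d1 <- sg_deriv(wave, m = 1)
  period <- pw_period(wave)
  guard <- max(3L, round(0.015 * fs))           # 15 ms separation from peak
  sys_end <- round(0.45 * n)                     # late-systolic search limit

  # rotate indexing so the foot is position 1
  rot <- function(i) ((i - i_ft) %% n) + 1L
  unrot <- function(p) ((p - 1L + i_ft - 1L) %% n) + 1L
  yr <- y[unrot(seq_len(n))]
  d1r <- d1[unrot(seq_len(n))]
  pkr <- rot(i_pk)

  pre <- NA_integer_
  if (pkr > 2L * guard) {
    lo <- guard; hi <- pkr - guard
    if (hi > lo) {
      seg <- lo:hi
      # prefer a local maximum of the signal itself (true early peak)
      lm <- local_maxima(yr[seg])
      if (length(lm)) {
        pre <- seg[lm[which.max(yr[seg][lm])]]
      } else {
        cand <- local_minima(d1r[seg])
        if (length(cand)) {
          k <- cand[which.min(d1r[seg][cand])]
          # require a genuine slowdown relative to the upstroke
          if (d1r[seg][k] < 0.6 * max(d1r)) pre <- seg[k]
        }
      }
    }
  }

  post <- NA_integer_
  lo <- pkr + guard; hi <- min(sys_end, n - guard)
  if (hi > lo) {
    seg <- lo:hi
    lm <- local_maxima(yr[seg])
    if (length(lm)) {
      post <- seg[lm[which.max(yr[seg][lm])]]
    } else {
      cand <- local_maxima(d1r[seg])
      if (length(cand)) post <- seg[cand[which.max(d1r[seg][cand])]]
    }
  }

  list(pre = if (is.na(pre)) NULL else unrot(pre),
       post = if (is.na(post)) NULL else unrot(post))
}

#' Pressure-beat fiducials: P1, P2 and wave type
#'
#' Locates the early (`P1`) and late (`P2`) systolic pressure landmarks of a
#' single pressure beat.  Depending on the wave type, the landmarks are the
#' systolic peak and a systolic shoulder found from the smoothed derivative:
#' type A waves have an early shoulder followed by a higher reflected peak
#' (`P2 > P1`), type B an early shoulder with `P2 <= P1`, and type C a late
#' shoulder after the systolic peak (augmentation `P2 - P1 < 0` allowed).
#' When no shoulder is detectable, `P1 = P2 =` systolic peak and the result
#' is flagged degenerate.
#'
#' @param wave a pressure [pulse_wave].
#' @return list of class `fiducials_pressure`: `foot_time`,
#'   `systolic_peak_time`, `systolic_peak`, `P1`, `P2`, `P1_time`, `P2_time`,
#'   `wave_type` (`"A"`, `"B"`, `"C"`), `degenerate` flag.
#' @export
pressure_inflections <- function(wave) {
  y <- wave$samples
  n <- length(y)
  fs <- wave$fs
  foot <- pulse_foot(wave)
  i_ft <- (round(foot * fs) %% n) + 1L
  i_pk <- which.max(y)
  sh <- find_shoulders(wave, i_ft, i_pk)

  t_of <- function(i) (i - 1) / fs
  degenerate <- FALSE
  if (!is.null(sh$pre)) {
    P1 <- y[sh$pre]; P2 <- y[i_pk]
    P1_t <- t_of(sh$pre); P2_t <- t_of(i_pk)
    wave_type <- if (P2 > P1) "A" else "B"
  } else if (!is.null(sh$post)) {
    P1 <- y[i_pk]; P2 <- y[sh$post]
    P1_t <- t_of(i_pk); P2_t <- t_of(sh$post)
    wave_type <- "C"
  } else {
    P1 <- P2 <- y[i_pk]
    P1_t <- P2_t <- t_of(i_pk)
    wave_type <- "C"
    degenerate <- TRUE
  }

  structure(list(foot_time = foot,
                 systolic_peak_time = t_of(i_pk), systolic_peak = y[i_pk],
                 P1 = P1, P2 = P2, P1_time = P1_t, P2_time = P2_t,
                 wave_type = wave_type, degenerate = degenerate),
            class = "fiducials_pressure")
}

#' @export
print.fiducials_pressure <- function(x, ...) {
  cat(sprintf("<fiducials_pressure> foot %.3f s, peak %.4g @ %.3f s, P1=%.4g, P2=%.4g, type %s%s\n",
              x$foot_time, x$systolic_peak, x$systolic_peak_time,
              x$P1, x$P2, x$wave_type,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

# --- PPG landmarks ---------------------------------------------------------

#' PPG-beat landmarks
#'
#' Normalises the beat to `[0, 1]` and locates: the systolic peak amplitude
#' `s`; the diastolic peak amplitude `dia` (first local maximum after the
#' dicrotic region; when the diastolic peak has vanished, the fallback is
#' the inflection point, i.e. the local maximum of the first derivative in
#' diastole, and `dia_found` is `FALSE`); their time difference `delta_T`;
#' and the early/late systolic shoulder amplitudes `PT1`/`PT2` (same
#' shoulder logic as for pressure beats).
#'
#' @param wave a PPG [pulse_wave] (any modality accepted; min-max range must
#'   be positive).
#' @return list of class `fiducials_ppg`: `foot_time`, `s`, `s_time`, `dia`,
#'   `dia_time`, `dia_found`, `delta_T`, `PT1`, `PT2`.
#' @export
ppg_landmarks <- function(wave) {
  x <- wave$samples
  rng <- max(x) - min(x)
  if (rng <= 0) stop("PPG beat has zero amplitude range")
  y <- (x - min(x)) / rng
  wv <- pw_replace(wave, y)
  n <- length(y)
  fs <- wave$fs

  foot <- pulse_foot(wv)
  i_ft <- (round(foot * fs) %% n) + 1L
  i_s <- which.max(y)
  t_of <- function(i) (i - 1) / fs

  # rotated view starting at the foot; the diastolic search window runs
  # from 40% of the beat after the foot (past end of systole, so that
  # late-systolic reflection features are not mistaken for the diastolic
  # peak) to 95% of the beat
  rot <- function(p) ((p - 1L + i_ft - 1L) %% n) + 1L
  after <- rot(seq_len(n))
  ya <- y[after]
  lo <- max(3L, round(0.32 * n)); hi <- round(0.95 * n)
  lo <- max(lo, which.max(ya) + max(3L, round(0.05 * n)))  # stay past the peak
  dia_found <- FALSE
  dia <- NA_real_; i_dia <- NA_integer_
  if (hi > lo + 2L) {
    seg <- lo:hi
    maxima <- local_maxima(ya[seg])
    if (length(maxima)) {
      # the most prominent diastolic local maximum: robust against small
      # residual wiggles that survive filtering
      prom <- peak_prominence(ya[seg], maxima)
      i_dia <- after[seg[maxima[which.max(prom)]]]
      dia <- y[i_dia]
      dia_found <- TRUE
    }
    if (!dia_found) {
      # fallback: diastolic inflection = local max of the first derivative
      d1 <- sg_deriv(wv, m = 1)
      d1a <- d1[after]
      cand <- local_maxima(d1a[seg])
      if (length(cand)) {
        i_dia <- after[seg[cand[1]]]
        dia <- y[i_dia]
      }
    }
  }
  delta_T <- if (!is.na(i_dia))
    wrap_delay(t_of(i_s), t_of(i_dia), pw_period(wave)) else NA_real_

  sh <- find_shoulders(wv, i_ft, i_s)
  PT1 <- PT2 <- NA_real_
  if (!is.null(sh$pre)) { PT1 <- y[sh$pre]; PT2 <- y[i_s] }
  else if (!is.null(sh$post)) { PT1 <- y[i_s]; PT2 <- y[sh$post] }
  else { PT1 <- PT2 <- y[i_s] }

  structure(list(foot_time = foot, s = y[i_s], s_time = t_of(i_s),
                 dia = dia, dia_time = if (is.na(i_dia)) NA_real_ else t_of(i_dia),
                 dia_found = dia_found, delta_T = delta_T,
                 PT1 = PT1, PT2 = PT2),
            class = "fiducials_ppg")
}

#' @export
print.fiducials_ppg <- function(x, ...) {
  cat(sprintf("<fiducials_ppg> s=%.3f @ %.3f s, dia=%.3f%s, dT=%.3f s, PT1=%.3f, PT2=%.3f\n",
              x$s, x$s_time, x$dia,
              if (x$dia_found) "" else " (inflection fallback)",
              x$delta_T, x$PT1, x$PT2))
  invisible(x)
}

# --- second-derivative PPG (SDPPG) landmarks -------------------------------

#' Second-derivative PPG landmarks a-e
#'
#' Computes the second derivative of the smoothed, normalised PPG beat and
#' walks the alternating extrema after the pulse foot: `a` the first
#' prominent maximum (early systolic positive wave), `b` the following
#' minimum, `c` the next maximum, `d` the next minimum and `e` the next
#' maximum (early diastolic positive wave).  Landmarks that cannot be found
#' are returned as `NA`.
#'
#' @param wave a PPG [pulse_wave] with `fs >= 100` Hz.
#' @return list of class `fiducials_sdppg` with elements `times` and
#'   `values` (named numeric vectors over `a`..`e`, second-derivative units
#'   of the normalised beat, 1/s^2).
#' @export
sdppg_landmarks <- function(wave) {
  if (wave$fs < 100) stop("sdppg_landmarks needs fs >= 100 Hz")
  x <- wave$samples
  rng <- max(x) - min(x)
  if (rng <= 0) stop("PPG beat has zero amplitude range")
  y <- (x - min(x)) / rng
  wv <- pw_replace(wave, y)
  n <- length(y)
  fs <- wave$fs
  foot <- pulse_foot(wv)
  # start the window slightly before the foot: the a-wave (upstroke onset
  # curvature) peaks just before the intersecting-tangent foot time
  lead <- round(0.04 * n)
  i_0 <- ((round(foot * fs) - lead) %% n) + 1L
  # second derivatives amplify high-frequency content, so a much wider
  # smoothing window (150 ms) is used here than for first-derivative
  # landmarks: the a-e curvature waves live well below 10 Hz
  d2 <- sg_deriv(wv, m = 2, ms = 150)
  idx <- ((seq_len(n) - 1L + i_0 - 1L) %% n) + 1L
  d2r <- d2[idx]
  win <- seq_len(round(0.85 * n))
  # smoothing leaves tiny curvature ripples; only extrema with at least 1%
  # of the dominant curvature magnitude count as landmarks
  thr <- 0.01 * max(abs(d2r[win]))

  # a: the dominant early maximum of the second derivative
  early <- seq_len(round(0.3 * n))
  i_a <- early[which.max(d2r[early])]

  nm <- c("a", "b", "c", "d", "e")
  pos <- stats::setNames(rep(NA_integer_, 5), nm)
  pos["a"] <- i_a
  cur <- i_a
  want_min <- TRUE
  for (k in 2:5) {
    if (cur >= max(win)) break
    seg <- (cur + 1L):max(win)
    cand <- if (want_min) local_minima(d2r[seg]) else local_maxima(d2r[seg])
    cand <- cand[abs(d2r[seg][cand]) >= thr]
    if (!length(cand)) break
    cur <- seg[cand[1]]
    pos[nm[k]] <- cur
    want_min <- !want_min
  }

  # times are measured from beat start, unwrapped past the window origin so
  # that the ordering a < b < c < d < e holds even when the beat wraps
  t_of <- function(p) foot - lead / fs + (p - 1) / fs
  times <- stats::setNames(rep(NA_real_, 5), nm)
  values <- stats::setNames(rep(NA_real_, 5), nm)
  ok <- !is.na(pos)
  times[ok] <- vapply(pos[ok], t_of, 0)
  values[ok] <- d2r[pos[ok]]
  structure(list(times = times, values = values, foot_time = foot),
            class = "fiducials_sdppg")
}

#' @export
print.fiducials_sdppg <- function(x, ...) {
  cat("<fiducials_sdppg>\n")
  print(rbind(time = x$times, value = x$values))
  invisible(x)
}
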