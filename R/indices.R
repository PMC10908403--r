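#' Foot-to-foot transit-time pulse wave velocity
#'
#' Detects the foot of each beat with the intersecting-tangent method, wraps
#' the transit time into `(0, period)` (the beats are periodic single
#' cycles) and divides the path distance by it.
#'
#' @param wave_a,wave_b proximal and distal [pulse_wave]s sharing `fs`.
#' @param delta_x path distance between the two sites in m (> 0).
#' @return PWV in m/s, with attribute `reliable = FALSE` when the transit
#'   time is below 2 sample intervals.
#' @export
transit_time_pwv <- function(wave_a, wave_b, delta_x) {
  stopifnot(delta_x > 0)
  if (wave_a$fs != wave_b$fs) stop("waves must share the sampling frequency")
  period <- max(pw_period(wave_a), pw_period(wave_b))
  dt <- wrap_delay(pulse_foot(wave_a), pulse_foot(wave_b), period)
  pwv <- delta_x / dt
  if (dt < 2 / wave_a$fs) attr(pwv, "reliable") <- FALSE
  pwv
}

#' Pulse pressure of a beat
#'
#' Maximum minus minimum of the pressure beat (systolic minus diastolic
#' pressure).
#'
#' @param wave a pressure [pulse_wave].
#' @return pulse pressure in Pa.
#' @export
pulse_pressure <- function(wave) {
  if (wave$modality != "pressure")
    stop("pulse_pressure requires a pressure wave")
  max(wave$samples) - min(wave$samples)
}

#' Augmentation pressure and augmentation index
#'
#' `AP = P2 - P1` (negative for type-C waves) and `AIx = AP / PP`.
#'
#' @param fids a `fiducials_pressure` object from [pressure_inflections()].
#' @param pp pulse pressure in Pa (> 0).
#' @return list with `AP` (Pa), `AIx` (dimensionless ratio) and `degenerate`
#'   flag (copied from the fiducials: no detectable shoulder).
#' @export
augmentation <- function(fids, pp) {
  stopifnot(inherits(fids, "fiducials_pressure"), pp > 0)
  ap <- fids$P2 - fids$P1
  list(AP = ap, AIx = ap / pp, degenerate = isTRUE(fids$degenerate))
}

#' Wave separation of pressure into forward and backward components
#'
#' Estimates the characteristic wave speed from the ratio of summed squared
#' pressure and velocity increments, `c = (1/rho) sqrt(sum(dP^2) /
#' sum(dU^2))`, and separates the pressure into forward and backward waves
#' by cumulative sums of the half-combinations
#' `Pf = 1/2 sum(dP + rho c dU)`, `Pb = 1/2 sum(dP - rho c dU)` (both
#' starting at 0).  Amplitudes are max - min; the reflection magnitude is
#' `RM = Pb_amp / Pf_amp`.
#'
#' @param p pressure [pulse_wave] in Pa.
#' @param u flow-velocity [pulse_wave] in m/s, same length and fs.
#' @param rho blood density in kg/m^3.
#' @return object of class `wave_separation`: `Pf`, `Pb` ([pulse_wave]s),
#'   `c` (m/s), `Pf_amp`, `Pb_amp` (Pa), `RM`.
#' @export
wave_separation <- function(p, u, rho = 1060) {
  if (length(p) != length(u)) stop("p and u must have equal length")
  if (p$fs != u$fs) stop("p and u must share the sampling frequency")
  dP <- diff(p$samples)
  dU <- diff(u$samples)
  if (sum(dU^2) == 0) stop("flow velocity is constant; wave speed undefined")
  cc <- sqrt(sum(dP^2) / sum(dU^2)) / rho
  pf <- c(0, cumsum((dP + rho * cc * dU) / 2))
  pb <- c(0, cumsum((dP - rho * cc * dU) / 2))
  pf_amp <- max(pf) - min(pf)
  pb_amp <- max(pb) - min(pb)
  structure(list(Pf = pw_replace(p, pf), Pb = pw_replace(p, pb),
                 c = cc, Pf_amp = pf_amp, Pb_amp = pb_amp,
                 RM = pb_amp / pf_amp),
            class = "wave_separation")
}

#' @export
print.wave_separation <- function(x, ...) {
  cat(sprintf("<wave_separation> c=%.2f m/s, Pf_amp=%.4g Pa, Pb_amp=%.4g Pa, RM=%.3f\n",
              x$c, x$Pf_amp, x$Pb_amp, x$RM))
  invisible(x)
}

#' Cardio-ankle vascular index
#'
#' `CAVI = c1 ln(SBP/DBP) (2 rho / PP) haPWV^2 + c2`, with brachial systolic
#' and diastolic pressure, brachial pulse pressure and the heart-ankle PWV,
#' all in SI units.  The empirical coefficients default to `c1 = 1`,
#' `c2 = 0` and are configurable.
#'
#' @param sbp,dbp brachial systolic/diastolic pressure in Pa
#'   (`sbp > dbp > 0`).
#' @param pp brachial pulse pressure in Pa (> 0).
#' @param ha_pwv heart-ankle PWV in m/s.
#' @param rho blood density in kg/m^3.
#' @param c1,c2 empirical coefficients.
#' @return CAVI (dimensionless).
#' @export
cavi <- function(sbp, dbp, pp, ha_pwv, rho = 1060, c1 = 1, c2 = 0) {
  if (!(sbp > dbp && dbp > 0 && pp > 0))
    stop("non-physical pressures for CAVI")
  c1 * log(sbp / dbp) * (2 * rho / pp) * ha_pwv^2 + c2
}

#' Carotid distensibility coefficient
#'
#' `DC = (dA / A_dia) / bPP`: relative change of carotid luminal area over a
#' cardiac cycle per unit brachial pulse pressure.
#'
#' @param delta_a area change (max - min) in m^2.
#' @param a_dia diastolic (minimum) area in m^2 (> 0).
#' @param bpp brachial pulse pressure in Pa (> 0).
#' @return DC in 1/Pa.
#' @export
distensibility <- function(delta_a, a_dia, bpp) {
  stopifnot(a_dia > 0, bpp > 0)
  (delta_a / a_dia) / bpp
}

#' PPG-derived index panel
#'
#' Computes the five PPG indices from landmark sets:
#' reflection index `RI = s / dia`, stiffness index `SI = H / delta_T`
#' (m/s), aging index `AGI = (b - c - d - e) / a`, PPG augmentation index
#' `AIx_ppg = PT2 / PT1` and `d/a`, using signed second-derivative values.
#'
#' The reflection-index orientation `s/dia` rises with stiffness as the
#' diastolic wave attenuates; set `ri_orientation = "dia_over_s"` for the
#' in vivo convention.
#'
#' @param fids a `fiducials_ppg` from [ppg_landmarks()].
#' @param sd a `fiducials_sdppg` from [sdppg_landmarks()].
#' @param height subject height in m.
#' @param ri_orientation `"s_over_dia"` (default) or `"dia_over_s"`.
#' @return named list `RI_ppg`, `SI_ppg`, `AGI`, `AIx_ppg`, `d_over_a`
#'   (`NA` where the needed landmarks are missing).
#' @export
ppg_panel <- function(fids, sd, height,
                      ri_orientation = c("s_over_dia", "dia_over_s")) {
  ri_orientation <- match.arg(ri_orientation)
  stopifnot(inherits(fids, "fiducials_ppg"), inherits(sd, "fiducials_sdppg"),
            height > 0)
  ri <- if (!is.na(fids$dia) && fids$dia > 0) {
    if (ri_orientation == "s_over_dia") fids$s / fids$dia
    else fids$dia / fids$s
  } else NA_real_
  si <- if (!is.na(fids$delta_T) && fids$delta_T > 0)
    height / fids$delta_T else NA_real_
  v <- sd$values
  agi <- if (!anyNA(v)) (v["b"] - v["c"] - v["d"] - v["e"]) / v["a"] else NA_real_
  aix <- if (!is.na(fids$PT1) && fids$PT1 > 0) fids$PT2 / fids$PT1 else NA_real_
  doa <- if (!anyNA(v[c("a", "d")])) v[["d"]] / v[["a"]] else NA_real_
  list(RI_ppg = unname(ri), SI_ppg = unname(si), AGI = unname(agi),
       AIx_ppg = unname(aix), d_over_a = doa)
}

#' Compute the full 19-index panel for one subject
#'
#' Runs every index on the subject's waveforms: the six transit-time PWVs
#' (aortic from flow waves, carotid-femoral/brachial-ankle/carotid-brachial/
#' carotid-radial from pressure, finger-toe from the digital and ankle PPG),
#' central and brachial pulse pressure, augmentation pressure/index from the
#' aortic-root pressure, backward-wave amplitude and reflection magnitude
#' from wave separation at the root, CAVI, carotid distensibility, and the
#' five PPG indices from the digital PPG.  Path lengths come from
#' `subject$path_lengths`.  An index whose inputs are absent or degenerate
#' is returned as `NA` with a reason; other indices are unaffected.
#'
#' @param subject a [virtual_subject].
#' @param config optional list: `cavi_c1`, `cavi_c2`, `ri_orientation`.
#' @return an [index_panel].
#' @export
compute_panel <- function(subject, config = list()) {
  cfg <- utils::modifyList(list(cavi_c1 = 1, cavi_c2 = 0,
                                ri_orientation = "s_over_dia"), config)
  values <- c()
  missing <- c()
  add <- function(name, expr_fn) {
    res <- tryCatch(expr_fn(), error = function(e) e)
    if (inherits(res, "error") || is.null(res) || is.na(res)) {
      missing[[name]] <<- if (inherits(res, "error"))
        conditionMessage(res) else "input unavailable"
    } else values[[name]] <<- res
  }
  need <- function(site, modality) {
    w <- subject_wave(subject, site, modality)
    if (is.null(w)) stop(site, " ", modality, " signal missing")
    w
  }
  pwv_pair <- function(site_a, mod_a, site_b, mod_b, pair) {
    dx <- subject$path_lengths[[pair]]
    if (is.null(dx) || is.na(dx)) stop("path length ", pair, " missing")
    transit_time_pwv(need(site_a, mod_a), need(site_b, mod_b), dx)
  }

  add("aoPWV", function()
    pwv_pair("aortic_root", "flow_velocity", "desc_aorta", "flow_velocity", "ao"))
  add("cfPWV", function() pwv_pair("carotid", "pressure", "femoral", "pressure", "cf"))
  add("baPWV", function() pwv_pair("brachial", "pressure", "ankle", "pressure", "ba"))
  add("cbPWV", function() pwv_pair("carotid", "pressure", "brachial", "pressure", "cb"))
  add("crPWV", function() pwv_pair("carotid", "pressure", "radial", "pressure", "cr"))
  add("ftPWV", function() pwv_pair("digital", "ppg", "ankle", "ppg", "ft"))

  add("cPP", function() pulse_pressure(need("aortic_root", "pressure")))
  add("bPP", function() pulse_pressure(need("brachial", "pressure")))

  root_fids <- tryCatch(
    pressure_inflections(need("aortic_root", "pressure")),
    error = function(e) e)
  add("AP", function() {
    if (inherits(root_fids, "error")) stop(conditionMessage(root_fids))
    augmentation(root_fids, pulse_pressure(need("aortic_root", "pressure")))$AP
  })
  add("AIx", function() {
    if (inherits(root_fids, "error")) stop(conditionMessage(root_fids))
    augmentation(root_fids, pulse_pressure(need("aortic_root", "pressure")))$AIx
  })

  ws <- tryCatch(
    wave_separation(need("aortic_root", "pressure"),
                    need("aortic_root", "flow_velocity"), subject$rho),
    error = function(e) e)
  add("Pb_amp", function() {
    if (inherits(ws, "error")) stop(conditionMessage(ws)); ws$Pb_amp
  })
  add("RM", function() {
    if (inherits(ws, "error")) stop(conditionMessage(ws)); ws$RM
  })

  add("CAVI", function() {
    bp <- need("brachial", "pressure")$samples
    ha <- pwv_pair("aortic_root", "pressure", "ankle", "pressure", "ha")
    cavi(max(bp), min(bp), max(bp) - min(bp), ha, subject$rho,
         cfg$cavi_c1, cfg$cavi_c2)
  })

  add("DC", function() {
    a <- need("carotid", "area")$samples
    bpp <- pulse_pressure(need("brachial", "pressure"))
    distensibility(max(a) - min(a), min(a), bpp)
  })

  ppg_fids <- tryCatch(ppg_landmarks(need("digital", "ppg")),
                       error = function(e) e)
  ppg_sd <- tryCatch(sdppg_landmarks(need("digital", "ppg")),
                     error = function(e) e)
  pp_panel <- if (inherits(ppg_fids, "error") || inherits(ppg_sd, "error"))
    NULL else ppg_panel(ppg_fids, ppg_sd, subject$height, cfg$ri_orientation)
  for (nm in c("RI_ppg", "SI_ppg", "AGI", "AIx_ppg", "d_over_a")) {
    local({
      nm2 <- nm
      add(nm2, function() {
        if (is.null(pp_panel)) stop("digital ppg signal missing or unusable")
        pp_panel[[nm2]]
      })
    })
  }

  index_panel(unlist(values), unlist(missing))
}
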