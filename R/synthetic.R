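# Wall-law constants used for synthetic subjects.  k1/k2 follow the CGS
# literature values converted to SI (2e7 g s^-2 cm^-1 -> 2e6 Pa,
# -22.53 cm^-1 -> -2253 m^-1); k3 is a free reference scaled by the aging law.
SYN_K1 <- 2e6        # Pa
SYN_K2 <- -2253      # 1/m
SYN_K3_REF <- 1e5    # Pa
SYN_PERIPH_K3 <- 1.3 # peripheral arteries stiffer than the aorta
SYN_DBP <- 70 * 133.322      # baseline diastolic pressure, Pa
SYN_U_PEAK <- 0.9            # baseline peak aortic flow velocity, m/s
SYN_REFL_SITE <- 0.6         # effective distance to reflection site, m
SYN_DIA_SITE <- 1.3          # distance scale setting the diastolic PPG wave, m
SYN_RHO <- 1060              # blood density, kg/m^3

# linear aging law for the k3 multiplier; spans E_Ao ~ 0.4-1.3 MPa over 25-75 yr
stiffness_aging <- function(age) 0.6 + 0.025 * (age - 25)

#' Specification of a synthetic virtual population
#'
#' Collects the physiological dials of the synthetic generator: heart rate,
#' stroke volume, duration of systole, arterial stiffness, reflection
#' strength, diastolic PPG wave amplitude, plus geometry scalers used by the
#' sensitivity analysis (large-artery diameter, peripheral vascular
#' resistance).  Defaults describe a mid-aged healthy subject.
#'
#' @param n_subjects number of subjects to generate (>= 1).
#' @param age_range two ages in years; subjects are drawn uniformly in it.
#' @param hr heart rate in beats/min.
#' @param stroke_volume_scale multiplier on the aortic flow amplitude.
#' @param systole_fraction fraction of the cardiac period spent in systole,
#'   in (0, 1).
#' @param stiffness_scale multiplier applied to the wall-law constant `k3`.
#' @param reflection_gain amplitude of the backward (reflected) pressure wave
#'   relative to the forward wave, in `[0, 1)`.
#' @param diastolic_ppg_gain amplitude of the diastolic PPG wave at age 25,
#'   in `[0, 1]`; it decays linearly to 0 at age 75.
#' @param diameter_scale multiplier on all luminal radii.
#' @param pvr_scale peripheral-vascular-resistance multiplier; raises
#'   diastolic pressure and reflection strength.
#' @param height subject height in m.
#' @param fs sampling frequency in Hz (>= 100; default 500).
#' @param seed integer seed for the population generator.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = 100, age_range = c(25, 75),
                           hr = 70, stroke_volume_scale = 1,
                           systole_fraction = 0.35,
                           stiffness_scale = 1, reflection_gain = 0.35,
                           diastolic_ppg_gain = 0.45,
                           diameter_scale = 1, pvr_scale = 1,
                           height = 1.75, fs = 500, seed = 1) {
  stopifnot(n_subjects >= 1, fs >= 100,
            length(age_range) == 2, age_range[1] <= age_range[2],
            hr > 0, stroke_volume_scale > 0,
            systole_fraction > 0, systole_fraction < 1,
            stiffness_scale > 0,
            reflection_gain >= 0, reflection_gain < 1,
            diastolic_ppg_gain >= 0, diastolic_ppg_gain <= 1,
            diameter_scale > 0, pvr_scale > 0, height > 0)
  structure(list(n_subjects = as.integer(n_subjects), age_range = age_range,
                 hr = hr, stroke_volume_scale = stroke_volume_scale,
                 systole_fraction = systole_fraction,
                 stiffness_scale = stiffness_scale,
                 reflection_gain = reflection_gain,
                 diastolic_ppg_gain = diastolic_ppg_gain,
                 diameter_scale = diameter_scale, pvr_scale = pvr_scale,
                 height = height, fs = fs, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> n=%d, ages %g-%g yr, hr=%g bpm, fs=%g Hz, seed=%d\n",
              x$n_subjects, x$age_range[1], x$age_range[2], x$hr, x$fs, x$seed))
  invisible(x)
}

# ---------------------------------------------------------------------------
# geometry

# build the arterial tree for one subject; returns aortic path, per-site
# segment paths, per-site one-way transit delays and path lengths
synthetic_tree <- function(spec, stiffness_scale, rho = SYN_RHO) {
  hscale <- spec$height / 1.75
  dscale <- spec$diameter_scale
  k3_ao <- SYN_K3_REF * stiffness_scale
  k3_pe <- k3_ao * SYN_PERIPH_K3

  seg_chain <- function(total_len, r_from, r_to, n, k3) {
    lens <- rep(total_len / n, n) * hscale
    rr <- seq(r_from, r_to, length.out = n + 1) * dscale
    lapply(seq_len(n), function(i)
      arterial_segment(lens[i], rr[i], rr[i + 1], SYN_K1, SYN_K2, k3))
  }

  aorta <- seg_chain(0.51, 0.0135, 0.006, 10, k3_ao)
  carotid <- seg_chain(0.15, 0.004, 0.003, 2, k3_pe)
  brach  <- seg_chain(0.36, 0.0045, 0.0035, 2, k3_pe)
  rad    <- seg_chain(0.26, 0.0035, 0.0025, 2, k3_pe)
  dig    <- seg_chain(0.10, 0.002, 0.0015, 1, k3_pe)
  iliac  <- seg_chain(0.20, 0.005, 0.004, 1, k3_pe)
  leg    <- seg_chain(0.55, 0.004, 0.0025, 2, k3_pe)

  site_paths <- list(
    aortic_root = list(),
    desc_aorta = aorta[1:3],
    carotid = c(aorta[1], carotid),
    brachial = c(aorta[1:2], brach),
    radial = c(aorta[1:2], brach, rad),
    digital = c(aorta[1:2], brach, rad, dig),
    femoral = c(aorta, iliac),
    ankle = c(aorta, iliac, leg))

  path_len <- vapply(site_paths, function(p)
    sum(vapply(p, function(s) s$length, 0)), 0)
  site_delays <- vapply(site_paths, function(p) {
    if (!length(p)) return(0)
    sum(vapply(p, function(s) s$length, 0) / segment_wave_speeds(p, rho))
  }, 0)

  pairs <- c(ao = "desc_aorta", cf = "femoral", ba = "ankle", cb = "brachial",
             cr = "radial", ft = "ankle", ha = "ankle")
  ref <- c(ao = "aortic_root", cf = "carotid", ba = "brachial",
           cb = "carotid", cr = "carotid", ft = "digital", ha = "aortic_root")
  path_lengths <- path_len[pairs] - path_len[ref]
  names(path_lengths) <- names(pairs)
  transit_delays <- site_delays[pairs] - site_delays[ref]
  names(transit_delays) <- names(pairs)

  list(aorta = aorta, site_paths = site_paths, path_lengths = path_lengths,
       site_delays = site_delays, transit_delays = transit_delays)
}

# ---------------------------------------------------------------------------
# root beat

# continuous forward-wave shape: raised-cosine upstroke over t_r, then a
# shifted exponential decay reaching 0 at the period end (continuous wrap)
forward_shape <- function(amp, t_rise, t_decay, period) {
  efac <- exp(-(period - t_rise) / t_decay)
  function(tau) {
    tau <- tau %% period
    up <- tau < t_rise
    out <- numeric(length(tau))
    out[up] <- amp * (1 - cos(pi * tau[up] / t_rise)) / 2
    out[!up] <- amp * (exp(-(tau[!up] - t_rise) / t_decay) - efac) / (1 - efac)
    out
  }
}

# shared core: builds the aortic-root beat for a given wave speed c.
# age_gain scales the reflection gain (reflections strengthen with age).
root_beat_core <- function(spec, c_root, rho = SYN_RHO, age_gain = 1) {
  period <- 60 / spec$hr
  fs <- spec$fs
  n <- round(period * fs)
  t <- (seq_len(n) - 1) / fs
  t_sys <- spec$systole_fraction * period
  t_rise <- 0.20 * t_sys
  t_decay <- 0.50 * period
  onset <- 0.10 * period            # upstroke start; beat begins before it
  tau_b <- 2 * SYN_REFL_SITE * spec$height / 1.75 / c_root
  if (tau_b < 2 / fs)
    stop("reflection delay shorter than 2 sample intervals")
  gain <- spec$reflection_gain * spec$pvr_scale * age_gain
  gain <- max(0, min(gain, 0.95))
  amp <- rho * c_root * SYN_U_PEAK * spec$stroke_volume_scale
  dbp <- SYN_DBP * sqrt(spec$pvr_scale)

  fshape <- forward_shape(amp, t_rise, t_decay, period)
  pf_fun <- function(tt) fshape(tt - onset)
  pb_fun <- function(tt) gain * fshape(tt - onset - tau_b)

  pf <- pf_fun(t); pb <- pb_fun(t)
  p <- pulse_wave(dbp + pf + pb, fs, "aortic_root", "pressure")
  u <- pulse_wave((pf - pb) / (rho * c_root), fs, "aortic_root",
                  "flow_velocity")

  # nominal foot by the intersecting-tangent construction on the
  # raised-cosine upstroke: max slope at t_rise/2, tangent meets the
  # pre-systolic minimum level at onset + (1/2 - 1/pi) t_rise
  foot_nominal <- onset + (0.5 - 1 / pi) * t_rise
  truth <- list(
    aoPWVt = c_root,
    forward_wave = pulse_wave(pf, fs, "aortic_root", "pressure"),
    backward_wave = pw_replace(p, pb),
    onset_time = foot_nominal,
    upstroke_start = onset,
    reflection_delay = tau_b,
    reflection_gain_eff = gain,
    dbp = dbp, rho = rho,
    systolic_rise = t_rise, period = period)
  list(pressure = p, flow = u, truth = truth,
       pf_fun = pf_fun, pb_fun = pb_fun)
}

#' Generate a single aortic-root beat
#'
#' Builds one cardiac cycle of aortic-root pressure and flow velocity from a
#' [synthetic_spec]: the pressure is diastolic pressure plus a forward wave
#' (raised-cosine upstroke, exponential decay) plus a backward wave (the
#' forward wave scaled by the reflection gain and delayed by a reflection
#' delay that shortens as stiffness grows); the flow velocity is the
#' water-hammer conjugate `(Pf - Pb) / (rho c)` with `c` the theoretical
#' aortic-root wave speed implied by `stiffness_scale`.
#'
#' @param spec a [synthetic_spec].
#' @param rho blood density in kg/m^3.
#' @return list with elements `pressure` and `flow` ([pulse_wave]s) and
#'   `truth` (partial ground truth: `aoPWVt`, the forward/backward component
#'   waves, the onset time, reflection delay and effective gain).
#' @export
make_root_beat <- function(spec, rho = SYN_RHO) {
  stopifnot(inherits(spec, "synthetic_spec"))
  tree <- synthetic_tree(spec, spec$stiffness_scale, rho)
  c_root <- theoretical_ao_pwv(tree$aorta[[1]], rho)
  out <- root_beat_core(spec, c_root, rho)
  out[c("pressure", "flow", "truth")]
}

# ---------------------------------------------------------------------------
# whole subject

# pulsatile amplification factors toward the periphery
SYN_SITE_AMP <- c(aortic_root = 1, desc_aorta = 1, carotid = 1,
                  brachial = 1.03, radial = 1.08, digital = 1.08,
                  femoral = 1.02, ankle = 1.05)

#' Generate one virtual subject with ground truth
#'
#' Builds a 10-segment aortic path plus peripheral branches with distally
#' tapering radii, assigns the wall-law constant `k3` scaled by the aging
#' law, propagates the aortic-root beat to each measurement site with the
#' exact per-segment transit delay (local thin-wall wave speeds) and a mild
#' peripheral pulse-pressure amplification, couples the carotid area wave
#' linearly to carotid pressure (so the true distensibility is
#' `1 / (rho c_carotid^2)`), and synthesises digital/ankle PPG as the
#' min-max-normalised local pressure plus an age-attenuated diastolic
#' Gaussian wave.
#'
#' @param spec a [synthetic_spec]; its `stiffness_scale` multiplies the
#'   aging law evaluated at `age`.
#' @param age subject age in years.
#' @param id subject identifier.
#' @param rho blood density in kg/m^3.
#' @return list with elements `subject` ([virtual_subject]) and `truth`
#'   (class `ground_truth`): `E_Ao` (Pa), `aoPWVt` (m/s), `transit_delays`
#'   (s, per site pair), `DC_true` (1/Pa), forward/backward waves, onset
#'   time, per-site delays and segment paths.
#' @export
make_subject <- function(spec, age, id = "s1", rho = SYN_RHO) {
  stopifnot(inherits(spec, "synthetic_spec"))
  sscale <- spec$stiffness_scale * stiffness_aging(age)
  tree <- synthetic_tree(spec, sscale, rho)
  c_root <- theoretical_ao_pwv(tree$aorta[[1]], rho)
  # wave reflections strengthen mildly with age
  age_gain <- 0.8 + 0.008 * (age - 25)
  rb <- root_beat_core(spec, c_root, rho, age_gain = age_gain)
  fs <- spec$fs
  n <- length(rb$pressure)
  t <- (seq_len(n) - 1) / fs
  dbp <- rb$truth$dbp

  waves <- list(
    aortic_root.pressure = rb$pressure,
    aortic_root.flow_velocity = rb$flow)

  press_at <- function(site) {
    d <- tree$site_delays[[site]]
    a <- SYN_SITE_AMP[[site]]
    dbp + a * (rb$pf_fun(t - d) + rb$pb_fun(t - d))
  }
  for (site in c("carotid", "brachial", "radial", "femoral", "ankle"))
    waves[[paste0(site, ".pressure")]] <-
      pulse_wave(press_at(site), fs, site, "pressure")

  # descending-aorta flow for aoPWV
  d_desc <- tree$site_delays[["desc_aorta"]]
  waves[["desc_aorta.flow_velocity"]] <- pulse_wave(
    (rb$pf_fun(t - d_desc) - rb$pb_fun(t - d_desc)) / (rho * c_root),
    fs, "desc_aorta", "flow_velocity")

  # carotid area linearly coupled to carotid pressure
  car_path <- tree$site_paths[["carotid"]]
  car_seg <- car_path[[length(car_path)]]
  c_car <- theoretical_ao_pwv(car_seg, rho)
  a_dia <- pi * ((car_seg$r_in + car_seg$r_out) / 2)^2
  p_car <- waves[["carotid.pressure"]]$samples
  waves[["carotid.area"]] <- pulse_wave(
    a_dia * (1 + (p_car - min(p_car)) / (rho * c_car^2)), fs,
    "carotid", "area")

  # digital and ankle PPG: normalised local pressure + diastolic wave
  dia_gain <- spec$diastolic_ppg_gain *
    max(0, min(1, (75 - age) / 50))
  t_dia_off <- rb$truth$systolic_rise + 2 * SYN_DIA_SITE / c_root
  sigma <- 0.05 * rb$truth$period
  for (site in c("digital", "ankle")) {
    d <- tree$site_delays[[site]]
    p_loc <- if (site == "digital") {
      a <- SYN_SITE_AMP[["digital"]]
      dbp + a * (rb$pf_fun(t - d) + rb$pb_fun(t - d))
    } else waves[["ankle.pressure"]]$samples
    base <- (p_loc - min(p_loc)) / (max(p_loc) - min(p_loc))
    tau <- (t - rb$truth$onset_time - d) %% rb$truth$period
    ppg <- base + dia_gain * exp(-(tau - t_dia_off)^2 / (2 * sigma^2))
    waves[[paste0(site, ".ppg")]] <- pulse_wave(ppg, fs, site, "ppg")
  }

  subject <- virtual_subject(id = id, age = age, height = spec$height,
                             rho = rho, aortic_path = tree$aorta,
                             path_lengths = tree$path_lengths, waves = waves)
  truth <- structure(list(
    E_Ao = aortic_young_modulus(tree$aorta),
    aoPWVt = c_root,
    transit_delays = tree$transit_delays,
    DC_true = 1 / (rho * c_car^2),
    forward_wave = rb$truth$forward_wave,
    backward_wave = rb$truth$backward_wave,
    onset_time = rb$truth$onset_time,
    reflection_delay = rb$truth$reflection_delay,
    reflection_gain_eff = rb$truth$reflection_gain_eff,
    dbp = dbp,
    site_delays = tree$site_delays,
    site_paths = tree$site_paths,
    diastolic_ppg_gain_eff = dia_gain), class = "ground_truth")
  list(subject = subject, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> E_Ao=%.3g Pa, aoPWVt=%.2f m/s, DC=%.3g 1/Pa\n",
              x$E_Ao, x$aoPWVt, x$DC_true))
  invisible(x)
}

#' Generate a synthetic virtual population
#'
#' Draws `spec$n_subjects` subjects with ages uniform over `spec$age_range`
#' and per-subject log-normal jitter of heart rate, stroke volume, stiffness,
#' arterial diameter and peripheral resistance, plus normal jitter of height.
#' Deterministic for a fixed `spec$seed`.
#'
#' @param spec a [synthetic_spec].
#' @param rho blood density in kg/m^3.
#' @return object of class `synthetic_population`: a list with elements
#'   `subjects` (list of [virtual_subject]) and `truths` (list of
#'   `ground_truth`), plus the generating `spec`.
#' @export
make_population <- function(spec, rho = SYN_RHO) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_subjects
  draws <- with_seed(spec$seed, list(
    age = runif(n, spec$age_range[1], spec$age_range[2]),
    hr = exp(rnorm(n, 0, 0.06)),
    sv = exp(rnorm(n, 0, 0.10)),
    stiff = exp(rnorm(n, 0, 0.08)),
    diam = exp(rnorm(n, 0, 0.05)),
    pvr = exp(rnorm(n, 0, 0.10)),
    height = rnorm(n, 0, 0.07)))
  subjects <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    si <- spec
    si$hr <- spec$hr * draws$hr[i]
    si$stroke_volume_scale <- spec$stroke_volume_scale * draws$sv[i]
    si$stiffness_scale <- spec$stiffness_scale * draws$stiff[i]
    si$diameter_scale <- spec$diameter_scale * draws$diam[i]
    si$pvr_scale <- spec$pvr_scale * draws$pvr[i]
    si$height <- spec$height + draws$height[i]
    ms <- make_subject(si, draws$age[i], id = sprintf("s%03d", i), rho = rho)
    subjects[[i]] <- ms$subject
    truths[[i]] <- ms$truth
  }
  structure(list(subjects = subjects, truths = truths, spec = spec),
            class = "synthetic_population")
}

#' @export
print.synthetic_population <- function(x, ...) {
  ages <- vapply(x$subjects, function(s) s$age, 0)
  eao <- vapply(x$truths, function(tr) tr$E_Ao, 0)
  cat(sprintf("<synthetic_population> %d subjects, ages %.0f-%.0f yr, E_Ao %.2g-%.2g Pa\n",
              length(x$subjects), min(ages), max(ages), min(eao), max(eao)))
  invisible(x)
}

# evaluate expr with a private RNG state, restoring the caller's state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
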