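test_that("transit-time PWV recovers an imposed delay exactly", {
  rb <- make_root_beat(synthetic_spec())
  w <- rb$pressure
  k <- 25                       # 25 samples = 0.05 s at 500 Hz
  delayed <- shift_wave(w, k)
  pwv <- transit_time_pwv(w, delayed, delta_x = 0.5)
  expect_equal(as.numeric(pwv), 0.5 / (k / w$fs), tolerance = 1e-9)
  # linear in the path length
  pwv2 <- transit_time_pwv(w, delayed, delta_x = 1.0)
  expect_equal(as.numeric(pwv2), 2 * as.numeric(pwv), tolerance = 1e-12)
  # sub-2-sample transit flagged unreliable
  pwv3 <- transit_time_pwv(w, shift_wave(w, 1), delta_x = 0.5)
  expect_false(isTRUE(attr(pwv3, "reliable")))
  expect_error(transit_time_pwv(w, pulse_wave(w$samples, 250, w$site,
                                              w$modality), 0.5),
               "sampling frequency")
})

test_that("pulse pressure is the beat range and offset-invariant", {
  ms <- test_subject()
  w <- subject_wave(ms$subject, "aortic_root", "pressure")
  pp <- pulse_pressure(w)
  expect_equal(pp, max(w$samples) - min(w$samples))
  w2 <- pulse_wave(w$samples + 2000, w$fs, w$site, w$modality)
  expect_equal(pulse_pressure(w2), pp)
  wc <- pulse_wave(rep(1e4, 100), 500, "carotid", "pressure")
  expect_equal(pulse_pressure(wc), 0)
  expect_error(pulse_pressure(subject_wave(ms$subject, "digital", "ppg")),
               "pressure")
})

test_that("PWV estimates are invariant to constant pressure offsets", {
  ms <- test_subject()
  a <- subject_wave(ms$subject, "carotid", "pressure")
  b <- subject_wave(ms$subject, "femoral", "pressure")
  p1 <- transit_time_pwv(a, b, 0.5)
  a$samples <- a$samples + 3000
  b$samples <- b$samples + 1234
  expect_equal(as.numeric(transit_time_pwv(a, b, 0.5)), as.numeric(p1),
               tolerance = 1e-12)
})

test_that("augmentation follows hand arithmetic", {
  fid <- structure(list(P1 = 13332, P2 = 14665.2, foot_time = 0,
                        systolic_peak_time = 0.2, systolic_peak = 14665.2,
                        P1_time = 0.1, P2_time = 0.2, wave_type = "A",
                        degenerate = FALSE),
                   class = "fiducials_pressure")
  aug <- augmentation(fid, pp = 6666.1)
  expect_equal(aug$AP, 1333.2)
  expect_equal(aug$AIx, 0.2, tolerance = 1e-4)
  fid$P2 <- fid$P1
  expect_equal(augmentation(fid, 6666.1)$AP, 0)
})

test_that("wave separation satisfies its algebraic identities", {
  set.seed(21)
  pop <- make_population(synthetic_spec(n_subjects = 10, seed = 77))
  for (i in 1:10) {
    s <- pop$subjects[[i]]
    p <- subject_wave(s, "aortic_root", "pressure")
    u <- subject_wave(s, "aortic_root", "flow_velocity")
    ws <- wave_separation(p, u, s$rho)
    pp <- pulse_pressure(p)
    rec <- ws$Pf$samples + ws$Pb$samples
    expect_lt(max(abs(rec - (p$samples - p$samples[1]))), 1e-9 * pp)
    expect_gt(ws$Pf_amp, 0)
    expect_gte(ws$RM, 0)
  }
})

test_that("a pure forward wave yields the exact speed and zero backward", {
  rb <- make_root_beat(synthetic_spec(reflection_gain = 0))
  c0 <- 11.3
  u <- pulse_wave(rb$pressure$samples / (1060 * c0), rb$pressure$fs,
                  "aortic_root", "flow_velocity")
  ws <- wave_separation(rb$pressure, u, 1060)
  expect_equal(ws$c, c0, tolerance = 1e-12)
  expect_lt(max(abs(ws$Pb$samples)), 1e-12 * ws$Pf_amp)
  expect_lt(ws$RM, 1e-12)
  uc <- pulse_wave(rep(1, length(rb$pressure)), rb$pressure$fs,
                   "aortic_root", "flow_velocity")
  expect_error(wave_separation(rb$pressure, uc, 1060), "constant")
})

test_that("CAVI reproduces the worked value and its limiting behaviour", {
  sbp <- convert_pressure(120, "mmHg", "Pa")
  dbp <- convert_pressure(80, "mmHg", "Pa")
  pp <- sbp - dbp
  expect_equal(cavi(sbp, dbp, pp, ha_pwv = 8, rho = 1060), 10.32,
               tolerance = 1e-3)
  expect_equal(cavi(sbp, dbp, pp, ha_pwv = 0, c2 = 3.1), 3.1)
  # quadratic dependence on the PWV
  base <- cavi(sbp, dbp, pp, 4)
  expect_equal(cavi(sbp, dbp, pp, 8), 4 * base, tolerance = 1e-12)
  expect_error(cavi(dbp, sbp, pp, 8), "non-physical")
})

test_that("distensibility follows its definition", {
  bpp <- convert_pressure(40, "mmHg", "Pa")
  expect_equal(distensibility(0.10 * 3e-5, 3e-5, bpp), 1.875e-5,
               tolerance = 1e-4)
  expect_equal(distensibility(0, 3e-5, bpp), 0)
})

test_that("PPG panel follows hand arithmetic and scale invariance", {
  fid <- structure(list(foot_time = 0.1, s = 1, s_time = 0.2, dia = 0.5,
                        dia_time = 0.45, dia_found = TRUE, delta_T = 0.25,
                        PT1 = 0.9, PT2 = 0.99),
                   class = "fiducials_ppg")
  sdv <- structure(list(times = c(a = .1, b = .15, c = .2, d = .25, e = .3),
                        values = c(a = 1, b = -1, c = -0.1, d = -0.2,
                                   e = 0.1)),
                   class = "fiducials_sdppg")
  pan <- ppg_panel(fid, sdv, height = 1.75)
  expect_equal(pan$SI_ppg, 7)
  expect_equal(pan$AGI, (-1 + 0.1 + 0.2 - 0.1) / 1)
  expect_equal(pan$RI_ppg, 2)
  expect_equal(pan$AIx_ppg, 0.99 / 0.9)
  expect_equal(pan$d_over_a, -0.2)
  # orientation flag
  expect_equal(ppg_panel(fid, sdv, 1.75, ri_orientation = "dia_over_s")$RI_ppg,
               0.5)
  # SI hand value: H = 1.75, dT = 0.25 -> 7 m/s
  fid$delta_T <- NA_real_
  expect_true(is.na(ppg_panel(fid, sdv, 1.75)$SI_ppg))
})

test_that("the full panel is complete on a full subject", {
  ms <- test_subject()
  pan <- compute_panel(ms$subject)
  expect_s3_class(pan, "index_panel")
  expect_false(anyNA(unclass(pan)))
  expect_length(attr(pan, "missing"), 0)
  expect_true(all(pan[c("aoPWV", "cfPWV", "baPWV", "cbPWV", "crPWV",
                        "ftPWV")] > 0))
  expect_gt(pan[["DC"]], 0)
})

test_that("removing a signal degrades exactly the indices that need it", {
  ms <- test_subject()
  s <- ms$subject
  s$waves[["ankle.ppg"]] <- NULL
  pan <- compute_panel(s)
  expect_true(is.na(pan[["ftPWV"]]))
  expect_match(attr(pan, "missing")[["ftPWV"]], "ankle ppg")
  # every other index is still there
  others <- setdiff(index_names(), "ftPWV")
  expect_false(anyNA(unclass(pan)[others]))

  s2 <- ms$subject
  s2$waves[["digital.ppg"]] <- NULL
  pan2 <- compute_panel(s2)
  ppg_idx <- c("ftPWV", "RI_ppg", "SI_ppg", "AGI", "AIx_ppg", "d_over_a")
  expect_true(all(is.na(unclass(pan2)[ppg_idx])))
  expect_false(anyNA(unclass(pan2)[setdiff(index_names(), ppg_idx)]))
})

test_that("a reflectionless subject yields RM 0 and degenerate augmentation", {
  ms <- make_subject(synthetic_spec(reflection_gain = 0), 50)
  pan <- compute_panel(ms$subject)
  expect_equal(pan[["RM"]], 0)
  expect_equal(pan[["AP"]], 0)
})

test_that("key indices track the reference stiffness across the population", {
  pop <- test_population()
  panels <- population_panels(pop)
  rs <- function(nm) cor(panels[[nm]], panels$E_Ao, use = "complete.obs",
                         method = "spearman")
  expect_gt(rs("cfPWV"), 0.95)
  expect_gt(rs("aoPWV"), 0.95)
  expect_gt(rs("CAVI"), 0.95)
  expect_lt(rs("DC"), -0.95)
  # stiffness sweep: cfPWV strictly increasing
  cf <- vapply(c(0.6, 1, 1.6, 2.2), function(sc) {
    ms <- make_subject(synthetic_spec(stiffness_scale = sc), 50)
    compute_panel(ms$subject)[["cfPWV"]]
  }, 0)
  expect_true(all(diff(cf) > 0))
})
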