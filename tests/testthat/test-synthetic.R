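test_that("root beat is deterministic and has the constructed anatomy", {
  spec <- synthetic_spec()
  rb1 <- make_root_beat(spec)
  rb2 <- make_root_beat(spec)
  expect_identical(rb1$pressure$samples, rb2$pressure$samples)
  expect_identical(rb1$flow$samples, rb2$flow$samples)
  # pressure = DBP + forward + backward
  expect_equal(rb1$pressure$samples,
               rb1$truth$dbp + rb1$truth$forward_wave$samples +
                 rb1$truth$backward_wave$samples,
               tolerance = 1e-12)
  # detected foot matches the stored nominal foot to well under 2 samples
  expect_lt(abs(pulse_foot(rb1$pressure) - rb1$truth$onset_time),
            2 / spec$fs)
})

test_that("no reflection means a vanishing backward wave and RM = 0", {
  spec <- synthetic_spec(reflection_gain = 0)
  rb <- make_root_beat(spec)
  expect_true(all(rb$truth$backward_wave$samples == 0))
  ws <- wave_separation(rb$pressure, rb$flow, 1060)
  expect_equal(ws$RM, 0)
  expect_equal(ws$c, rb$truth$aoPWVt, tolerance = 1e-9)
})

test_that("pulse pressure grows monotonically with the stiffness scale", {
  pp <- vapply(c(0.5, 1, 1.5, 2, 2.5), function(s) {
    rb <- make_root_beat(synthetic_spec(stiffness_scale = s))
    pulse_pressure(rb$pressure)
  }, 0)
  expect_true(all(diff(pp) > 0))
})

test_that("an extreme stiffness scale trips the reflection-delay guard", {
  expect_error(make_root_beat(synthetic_spec(stiffness_scale = 8000)),
               "reflection delay")
})

test_that("aging law produces strictly increasing aortic stiffness", {
  spec <- synthetic_spec()
  eao <- vapply(seq(25, 75, by = 5), function(a)
    make_subject(spec, a)$truth$E_Ao, 0)
  expect_true(all(diff(eao) > 0))
  expect_gt(eao[1], 3e5)   # ~0.4 MPa at 25 yr
  expect_lt(eao[length(eao)], 1.5e6)  # ~1.3 MPa at 75 yr
})

test_that("stored transit delays equal sums of L/c over the stored paths", {
  ms <- test_subject()
  tr <- ms$truth
  rho <- ms$subject$rho
  # independent loop over the stored per-site geometry
  delay_of <- function(site) {
    segs <- tr$site_paths[[site]]
    if (!length(segs)) return(0)
    total <- 0
    for (s in segs) {
      rbar <- (s$r_in + s$r_out) / 2
      eh <- rbar * (s$k1 * exp(s$k2 * rbar) + s$k3)
      total <- total + s$length / sqrt(2 * eh / (3 * rho * rbar))
    }
    total
  }
  fs <- ms$subject$waves[[1]]$fs
  expect_lt(abs((delay_of("femoral") - delay_of("carotid")) -
                  tr$transit_delays[["cf"]]), 1 / fs)
  expect_lt(abs(delay_of("ankle") - tr$transit_delays[["ha"]]), 1 / fs)
  expect_lt(abs(delay_of("desc_aorta") - tr$transit_delays[["ao"]]), 1 / fs)
})

test_that("foot-to-foot delays recover the stored transit delays", {
  ms <- test_subject()
  s <- ms$subject
  fs <- s$waves[[1]]$fs
  period <- length(s$waves[[1]]$samples) / fs
  pairs <- list(ao = c("aortic_root.flow_velocity", "desc_aorta.flow_velocity"),
                cf = c("carotid.pressure", "femoral.pressure"),
                ba = c("brachial.pressure", "ankle.pressure"),
                ft = c("digital.ppg", "ankle.ppg"),
                ha = c("aortic_root.pressure", "ankle.pressure"))
  for (p in names(pairs)) {
    dt <- (pulse_foot(s$waves[[pairs[[p]][2]]]) -
             pulse_foot(s$waves[[pairs[[p]][1]]])) %% period
    expect_lt(abs(dt - ms$truth$transit_delays[[p]]) * fs, 2,
              label = sprintf("pair %s delay error in samples", p))
  }
})

test_that("populations are deterministic, seed-sensitive, and age-stiffness linked", {
  spec <- synthetic_spec(n_subjects = 1, seed = 5)
  expect_length(make_population(spec)$subjects, 1)

  pop_a <- make_population(synthetic_spec(n_subjects = 6, seed = 5))
  pop_b <- make_population(synthetic_spec(n_subjects = 6, seed = 5))
  expect_identical(vapply(pop_a$truths, function(tr) tr$E_Ao, 0),
                   vapply(pop_b$truths, function(tr) tr$E_Ao, 0))
  pop_c <- make_population(synthetic_spec(n_subjects = 6, seed = 6))
  expect_false(identical(vapply(pop_a$truths, function(tr) tr$E_Ao, 0),
                         vapply(pop_c$truths, function(tr) tr$E_Ao, 0)))

  pop <- test_population()
  ages <- vapply(pop$subjects, function(s) s$age, 0)
  eao <- vapply(pop$truths, function(tr) tr$E_Ao, 0)
  expect_gt(cor(ages, eao, method = "spearman"), 0.9)
})

test_that("generated carotid area and brachial pressure recover DC_true", {
  for (age in c(30, 50, 70)) {
    ms <- make_subject(synthetic_spec(), age)
    a <- subject_wave(ms$subject, "carotid", "area")$samples
    bpp <- pulse_pressure(subject_wave(ms$subject, "brachial", "pressure"))
    dc <- distensibility(max(a) - min(a), min(a), bpp)
    expect_lt(abs(dc / ms$truth$DC_true - 1), 0.05)
  }
})

test_that("wave separation recovers the effective reflection gain within 2%", {
  pop <- test_population()
  for (i in seq(1, 40, by = 4)) {
    s <- pop$subjects[[i]]
    ws <- wave_separation(subject_wave(s, "aortic_root", "pressure"),
                          subject_wave(s, "aortic_root", "flow_velocity"),
                          s$rho)
    g <- pop$truths[[i]]$reflection_gain_eff
    expect_lt(abs(ws$RM - g) / g, 0.02)
  }
})

test_that("uniform-stiffness path stores E_Ao equal to the common E", {
  # all aortic segments share one k3 and k1 = 0: every segment has the same E
  segs <- lapply(1:10, function(i)
    arterial_segment(0.05, 0.012, 0.010, 0, 0, 0.15 * 9e5))
  expect_equal(aortic_young_modulus(segs), 9e5, tolerance = 1e-12)
})
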