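test_that("correlation handles linear, monotone and null relationships", {
  x <- seq(-2, 2, length.out = 50)
  r <- correlate(2 * x + 1, x)
  expect_equal(r$r_p, 1)
  expect_equal(r$r_s, 1)
  # monotone nonlinear: rank correlation saturates, linear does not
  r2 <- correlate(exp(x), x)
  expect_equal(r2$r_s, 1)
  expect_lt(r2$r_p, 1)
  # permuted independent draws stay near zero
  set.seed(31)
  a <- rnorm(1000); b <- rnorm(1000)
  r3 <- correlate(a, b)
  expect_lt(abs(r3$r_s), 0.08)
  # invariance of r_s under strictly increasing transforms
  ms <- test_population()
  panels <- population_panels(ms)
  r4 <- correlate(panels$cfPWV, panels$E_Ao)
  r5 <- correlate(log(panels$cfPWV), panels$E_Ao^3)
  expect_equal(r4$r_s, r5$r_s)
  expect_error(correlate(1:5, rep(1, 5)), "zero variance")
  expect_error(correlate(c(1, 2, NA), c(1, NA, 3)), "fewer than 3")
})

test_that("Bland-Altman reproduces hand-computed values", {
  x <- c(10, 20, 30)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_half_width, 0)
  ba1 <- bland_altman(x + 1.7, x)
  expect_equal(ba1$bias, 1.7)
  expect_equal(ba1$loa_half_width, 0)
  # differences {0.1, 0.3, 0.5}: population SD 0.16330, half width 0.32007
  ba2 <- bland_altman(x + c(0.1, 0.3, 0.5), x)
  expect_equal(ba2$bias, 0.3)
  expect_equal(ba2$loa_half_width, 0.32007, tolerance = 1e-4)
  # sample-SD convention switchable
  ba3 <- bland_altman(x + c(0.1, 0.3, 0.5), x, sample_sd = TRUE)
  expect_equal(ba3$loa_half_width, 1.96 * 0.2)
  expect_error(bland_altman(1, 1), "at least 2")
  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("sensitivity index evaluates its hand cases", {
  ages <- c(25, 35)
  base <- data.frame(age = ages, value = c(10, 20))
  grid <- expand.grid(age = ages, parameter = "heart rate",
                      direction = c(1, -1), stringsAsFactors = FALSE)
  # no response -> 0
  grid$value <- base$value[match(grid$age, base$age)]
  expect_equal(sensitivity_index(grid, base)$I, 0)
  # +5% under +1SD and -5% under -1SD -> 5
  grid$value <- base$value[match(grid$age, base$age)] *
    (1 + 0.05 * grid$direction)
  expect_equal(sensitivity_index(grid, base)$I, 5)
  # symmetric +5% both directions -> signed cancellation to 0
  grid$value <- base$value[match(grid$age, base$age)] * 1.05
  expect_equal(sensitivity_index(grid, base)$I, 0)
  base0 <- base; base0$value[1] <- 0
  expect_error(sensitivity_index(grid, base0), "zero")
})

test_that("the sensitivity harness identifies input PWV as a key driver", {
  sens <- run_sensitivity(synthetic_spec(), ages = c(35, 55, 75))
  expect_s3_class(sens, "va_sensitivity")
  expect_setequal(unique(sens$group), c("cardiac", "vascular"))
  pick <- function(idx, par) sens$I[sens$index == idx & sens$parameter == par]
  # stiffer wall law -> faster carotid-femoral transit
  expect_gt(pick("cfPWV", "input PWV"), 5)
  # cardiac dials barely touch cfPWV
  expect_lt(abs(pick("cfPWV", "heart rate")), 1)
  expect_lt(abs(pick("cfPWV", "stroke volume")), 1)
  # pulse pressures respond strongly to stroke volume
  expect_gt(pick("cPP", "stroke volume"), 10)
})

test_that("an infinite SNR level reproduces the clean correlations exactly", {
  pop <- test_population()
  clean <- noise_robustness(pop, snr_levels = Inf, seed = 1)
  panels <- population_panels(pop)
  for (nm in c("cfPWV", "DC", "CAVI")) {
    r <- correlate(panels[[nm]], panels$E_Ao)
    expect_equal(clean$r_s[clean$index == nm], r$r_s)
    expect_equal(clean$r_p[clean$index == nm], r$r_p)
  }
})

test_that("noise robustness tables are reproducible for a fixed seed", {
  pop <- make_population(synthetic_spec(n_subjects = 8, seed = 23))
  t1 <- noise_robustness(pop, snr_levels = c(30), seed = 5)
  t2 <- noise_robustness(pop, snr_levels = c(30), seed = 5)
  expect_identical(t1, t2)
  t3 <- noise_robustness(pop, snr_levels = c(30), seed = 6)
  expect_false(identical(t1$r_s, t3$r_s))
})

test_that("the full assessment bundles panels, correlations and agreement", {
  dir <- withr::local_tempdir()
  pop <- make_population(synthetic_spec(n_subjects = 12, seed = 19))
  res <- run_full_assessment(pop, spec = pop$spec, snr_levels = NULL,
                             sensitivity = FALSE, out_dir = dir)
  expect_s3_class(res, "va_assessment")
  expect_equal(nrow(res$panels), 12)
  expect_true(all(c("panels.csv", "correlations.csv", "bland_altman.csv")
                  %in% list.files(dir)))
  # correlations sorted by descending |r_s| within cohort
  tab <- res$correlations[res$correlations$cohort == "all", ]
  expect_true(all(diff(abs(tab$r_s)) <= 1e-12))
  # Bland-Altman against the theoretical reference for all six PWV indices
  expect_setequal(res$bland_altman$index,
                  c("aoPWV", "cfPWV", "baPWV", "cbPWV", "crPWV", "ftPWV"))
  expect_true(all(is.finite(res$bland_altman$bias)))
  expect_output(print(res), "va_assessment")
})

test_that("bland_altman of shifted data is exactly (k, 0)", {
  set.seed(12)
  x <- rnorm(40)
  ba <- bland_altman(x + 3.25, x)
  expect_equal(ba$bias, 3.25)
  expect_equal(ba$loa_half_width, 0)
})
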