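# shared fixtures, built once per test run

# small default-condition population reused across test files
test_population <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_population(synthetic_spec(n_subjects = 40, seed = 11))
    cache
  }
})

# a mid-aged subject with ground truth
test_subject <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_subject(synthetic_spec(), age = 55)
    cache
  }
})

# two-component PPG-like beat: Gaussian systolic + Gaussian diastolic wave
two_gaussian_beat <- function(amp1 = 1, t1 = 0.20, amp2 = 0.4, t2 = 0.45,
                              sigma = 0.035, fs = 500, duration = 0.9) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  y <- amp1 * exp(-(t - t1)^2 / (2 * sigma^2)) +
    amp2 * exp(-(t - t2)^2 / (2 * sigma^2))
  pulse_wave(y, fs, "digital", "ppg")
}

# circular shift by an integer number of samples
shift_wave <- function(wave, k) {
  n <- length(wave$samples)
  k <- k %% n
  if (k == 0) return(wave)
  s <- wave$samples
  wave$samples <- c(s[(n - k + 1):n], s[1:(n - k)])
  wave
}
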