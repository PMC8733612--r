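test_that("narrowband filtering concentrates variance in the analysis bin", {
  set.seed(1)
  x <- rnorm(120 * 250)
  y <- narrowband_filter(x, 8, 250)
  expect_gt(band_variance_fraction(y, 250, 7.5, 9.5), 0.8)
  expect_equal(narrowband_filter(numeric(10000), 8, 250), numeric(10000))
  # the top analysis bin is valid at the lowest supported sampling rate
  expect_silent(narrowband_filter(rnorm(3000), 44, 200))
})

test_that("the Hilbert envelope tracks amplitude", {
  fs <- 250
  t <- seq(0, 20, by = 1 / fs)
  env <- amplitude_envelope(3 * sin(2 * pi * 10 * t))
  core <- env[round(0.1 * length(env)):round(0.9 * length(env))]
  expect_equal(mean(core), 3, tolerance = 0.02)
  expect_true(all(abs(core - 3) < 0.06 + 0.02 * 3))
  expect_equal(amplitude_envelope(numeric(100)), numeric(100))

  m <- 1 + 0.5 * sin(2 * pi * 0.3 * t)     # slow modulator
  est <- amplitude_envelope(m * sin(2 * pi * 10 * t))
  core_idx <- round(0.1 * length(t)):round(0.9 * length(t))
  expect_lt(max(abs(est[core_idx] - m[core_idx])), 0.1)
})

test_that("DFA matches the brute-force oracle and the white-noise null", {
  fs <- 250
  vals <- vapply(1:3, function(k) {
    set.seed(30 + k)
    dfa_exponent(abs(rnorm(300 * fs)), fs, c(2, 20))$exponent
  }, 0)
  expect_equal(mean(vals), 0.5, tolerance = 0.05)

  env <- generate_fgn(0.75, 300 * fs, seed = 77)
  fit <- dfa_exponent(env, fs, c(2, 20))
  expect_equal(fit$exponent, 0.75, tolerance = 0.05)
  brute <- dfa_brute_force(env, fs, 2, 20)
  expect_lt(abs(fit$exponent - brute), 0.02)
  expect_gt(fit$fit_r2, 0.95)

  expect_error(dfa_exponent(rep(2, 30000), fs, c(2, 20)), "degenerate")
})

test_that("DFA is invariant to amplitude scaling", {
  env <- abs(generate_fgn(0.68, 30000, seed = 5)) + 0.5
  a <- dfa_exponent(env, 250, c(2, 20))$exponent
  b <- dfa_exponent(13.7 * env, 250, c(2, 20))$exponent
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("fE/I flags degenerate inputs and is scale invariant", {
  fs <- 250
  t <- seq(0, 200, by = 1 / fs)
  pure <- sin(2 * pi * 10 * t)
  r <- fei_value(pure, fs)
  expect_false(r$valid)

  sp <- signal_spec(150, fs, band = c(8, 13), hurst = 0.7, seed = 6)
  x <- bandpass_fir(generate_band_signal(sp), 8, 13, fs)
  r1 <- fei_value(x, fs)
  r2 <- fei_value(5.5 * x, fs)
  expect_equal(r1$fei, r2$fei, tolerance = 1e-10)
  expect_error(fei_value(x[1:1000], fs), "windows")
})

test_that("measure spectra have the 44-bin layout and localized effects", {
  fs <- 200
  # same construction, high vs low envelope Hurst exponent in 11-18 Hz
  make_rec <- function(h) {
    sig <- t(vapply(1:2, function(ch) {
      sp <- signal_spec(150, fs, band = c(11, 18), hurst = h,
                        osc_amplitude = 12, env_log_sd = 1, seed = 40 + ch)
      generate_band_signal(sp, confine = TRUE)
    }, numeric(150 * fs)))
    eeg_recording(sig, fs, c("C3", "C4"))
  }
  hi <- measure_spectrum(make_rec(0.85), "dfa")
  lo <- measure_spectrum(make_rec(0.55), "dfa")
  expect_equal(dim(hi$values), c(2, 44))
  expect_equal(hi$bins, 1:44)
  # the injected Hurst contrast shows inside the oscillation band ...
  expect_gt(mean(band_summary(hi, 12, 17)) - mean(band_summary(lo, 12, 17)),
            0.05)
  # ... and not in bins the oscillation does not occupy
  out_hi <- rowMeans(hi$values[, as.character(30:40)])
  out_lo <- rowMeans(lo$values[, as.character(30:40)])
  expect_lt(abs(mean(out_hi) - mean(out_lo)), 0.05)
})

test_that("band summaries are bin means over fully contained bins", {
  vals <- matrix(rep(1:44, each = 2), 2, 44,
                 dimnames = list(c("a", "b"), 1:44))
  ms <- structure(list(measure = "dfa", bins = 1:44, values = vals,
                       validity = matrix(TRUE, 2, 44)),
                  class = "measure_spectrum")
  expect_equal(unname(band_summary(ms, 11, 18)), rep(mean(11:17), 2))
  expect_error(band_summary(ms, 50, 60), "bins")
})

test_that("scale-range rule switches at the 8-Hz bin", {
  expect_equal(eispec:::dfa_scale_range(7), c(4, 20))
  expect_equal(eispec:::dfa_scale_range(8), c(2, 20))
})
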