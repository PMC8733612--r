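test_that("background-only signals have the requested 1/f slope", {
  sp <- signal_spec(120, 250, band = NULL, aperiodic_beta = 2,
                    aperiodic_offset = 1, seed = 5)
  x <- generate_band_signal(sp)
  ps <- welch_psd(x, 250)
  sel <- ps$frequencies >= 2 & ps$frequencies <= 40
  slope <- coef(lm(log10(ps$power[1, sel]) ~ log10(ps$frequencies[sel])))[2]
  expect_equal(unname(slope), -2, tolerance = 0.1)
})

test_that("signal specs validate their inputs", {
  expect_error(signal_spec(0, 250), "duration")
  expect_error(signal_spec(10, 250, hurst = 1.2), "hurst")
  expect_error(signal_spec(10, 250, band = c(10, 130)), "Nyquist")
  expect_error(signal_spec(10, 250, coupling_rho = 1.5), "coupling_rho")
})

test_that("band signals are reproducible and envelope Hurst is recovered", {
  sp <- signal_spec(60, 250, band = c(8, 13), hurst = 0.7, seed = 9)
  expect_identical(generate_band_signal(sp), generate_band_signal(sp))
  est <- vapply(1:4, function(k) {
    spk <- signal_spec(250, 250, band = c(8, 13), hurst = 0.75, seed = 100 + k)
    x <- generate_band_signal(spk)
    xb <- bandpass_fir(x, 8, 13, 250)
    dfa_exponent(amplitude_envelope(xb), 250, c(2, 20))$exponent
  }, 0)
  expect_equal(mean(est), 0.75, tolerance = 0.05)
})

test_that("artifact injection logs events with the requested properties", {
  rec <- quick_recording(19, duration = 300, fs = 200, seed = 3)
  out <- inject_artifacts(rec, list(blinks_per_min = 0, transients_per_min = 6,
                                    flat_prob = 0), seed = 1)
  nt <- sum(out$events$type == "transient")
  expect_gt(nt, 15)   # Poisson(30)
  expect_lt(nt, 50)
  ev <- out$events[out$events$type == "transient", ][1, ]
  seg <- out$recording$signal[match(ev$channel, rec$channel_labels),
                              ev$sample:(ev$sample + 20)]
  expect_gt(max(abs(seg)), 150)
})

test_that("zero artifact rates leave the recording untouched", {
  rec <- quick_recording(19, duration = 20, fs = 200, seed = 4)
  out <- inject_artifacts(rec, list(blinks_per_min = 0, transients_per_min = 0,
                                    flat_prob = 0), seed = 1)
  expect_identical(out$recording$signal, rec$signal)
  expect_equal(nrow(out$events), 0)
})

test_that("flat-channel probability one silences exactly one channel", {
  rec <- quick_recording(19, duration = 20, fs = 200, seed = 5)
  out <- inject_artifacts(rec, list(blinks_per_min = 0, transients_per_min = 0,
                                    flat_prob = 1), seed = 2)
  vars <- apply(out$recording$signal, 1, var)
  expect_equal(sum(vars == 0), 1)
})

test_that("cohorts have the configured size, montage and ground truth", {
  cs <- cohort_spec(n_control = 3, n_patient = 2, duration = 12,
                    sampling_rate = 200, seed = 8)
  coh <- generate_cohort(cs)
  expect_length(coh$recordings, 5)
  expect_equal(nrow(coh$ground_truth), 5)
  expect_equal(coh$recordings[[1]]$channel_labels, channels_1020())
  expect_equal(coh$ground_truth$group, c(rep("control", 3), rep("patient", 2)))
  sc <- coh$ground_truth$GMFCS[coh$ground_truth$group == "patient"]
  expect_true(all(is.na(sc) | (sc >= 1 & sc <= 5)))
  # patients carry positive injected offsets
  gt <- coh$ground_truth
  expect_true(all(gt$hurst_high[gt$group == "patient"] >
                    mean(gt$hurst_high[gt$group == "control"])))
  expect_error(cohort_spec(montage = c("Fp1", "Fp2")), "montage")
  expect_error(cohort_spec(n_control = 0), "positive")
})

test_that("identical cohort seeds give bit-identical recordings", {
  cs <- cohort_spec(n_control = 1, n_patient = 1, duration = 10,
                    sampling_rate = 200, seed = 21)
  a <- generate_cohort(cs)
  b <- generate_cohort(cs)
  expect_identical(a$recordings[[1]]$signal, b$recordings[[1]]$signal)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("analytic synthetic spectra follow the requested parameterization", {
  f <- seq(1, 30, by = 0.125)
  sp <- synthetic_spectrum(f, offset = 1.2, exponent = 1.8, noise_sd = 0)
  expect_equal(log10(sp$power[1, ]), 1.2 - 1.8 * log10(f), tolerance = 1e-12)
})
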