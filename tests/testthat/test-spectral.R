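test_that("FFT length follows the fs/0.125 rule giving a 0.125-Hz grid", {
  set.seed(1)
  ps <- welch_psd(rnorm(4 * 1000), 1000)
  expect_equal(ps$params$nfft, 8000)
  expect_equal(diff(ps$frequencies[1:2]), 0.125)
  # 353 bins inside 1-45 Hz
  expect_equal(sum(ps$frequencies >= 1 & ps$frequencies <= 45), 353)
})

test_that("Welch density integrates to the signal variance", {
  set.seed(2)
  x <- rnorm(300 * 250)
  ps <- welch_psd(x, 250)
  integral <- sum(ps$power[1, ]) * diff(ps$frequencies[1:2])
  expect_equal(integral, var(x), tolerance = 0.05)
  expect_true(all(welch_psd(numeric(5000), 250)$power == 0))
  expect_error(welch_psd(rnorm(100), 250), "at least")
})

test_that("segments never span a rejection gap in epoched input", {
  rec <- quick_recording(2, duration = 12, fs = 200, seed = 3,
                         labels = c("Cz", "Pz"))
  eps <- segment_and_reject(rec, 1e9)
  eps$keep_mask[6] <- FALSE   # two runs: 5 s and 6 s
  ps <- welch_psd(eps)
  # runs of 5 and 6 s give 4 + 5 half-overlapping 2-s segments
  expect_equal(ps$params$n_segments, 9)
})

test_that("band averages use the inclusive grid with snapped edges", {
  f <- seq(0, 50, by = 0.125)
  pw <- matrix(seq_along(f), 1)
  sp <- eispec:::new_psd_spectrum(pw, f)
  # 1.75..4.625 on the grid: 24 bins; printed upper edge 4.63 snaps down
  sel <- which(f >= 1.75 & f <= 4.625)
  expect_length(sel, 24)
  expect_equal(unname(band_average_power(sp, 1.75, 4.63)), mean(pw[1, sel]))
  cpw <- matrix(3.3, 1, length(f))
  expect_equal(unname(band_average_power(eispec:::new_psd_spectrum(cpw, f),
                                         8, 13)), 3.3)
  expect_error(band_average_power(sp, 60, 70), "bins")
})

test_that("whole-brain averaging is a channel mean invariant to order", {
  v <- c(5, rep(0, 18))
  expect_equal(whole_brain_average(v), 5 / 19)
  expect_equal(whole_brain_average(rep(2.5, 19)), 2.5)
  set.seed(4)
  m <- matrix(rnorm(19 * 4), 19)
  expect_equal(whole_brain_average(m), whole_brain_average(m[sample(19), ]))
})
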