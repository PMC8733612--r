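test_that("a pure power law is recovered essentially exactly", {
  f <- seq(1, 30, by = 0.125)
  fit <- fit_spectral_model(10^1.5 * f^(-2), frequencies = f)
  expect_equal(fit$exponent, 2, tolerance = 0.01)
  expect_equal(fit$offset, 1.5, tolerance = 0.01)
  expect_gt(fit$r2, 0.999)
  expect_length(fit$peaks, 0)
})

test_that("a Gaussian peak is recovered on top of the power law", {
  f <- seq(1, 30, by = 0.125)
  lp <- 1.5 - 2 * log10(f) + 0.5 * exp(-(f - 10)^2 / 2)
  fit <- fit_spectral_model(10^lp, frequencies = f)
  expect_gte(length(fit$peaks), 1)
  main <- fit$peaks[[which.max(vapply(fit$peaks, `[`, 0, "height"))]]
  expect_equal(unname(main["center"]), 10, tolerance = 0.25)
  expect_equal(fit$exponent, 2, tolerance = 0.05)
})

test_that("the 5-30 Hz sensitivity range gives a consistent exponent", {
  f <- seq(1, 30, by = 0.125)
  lp <- 1.2 - 1.6 * log10(f) + 0.4 * exp(-(f - 9)^2 / (2 * 1.5^2))
  a <- fit_spectral_model(10^lp, frequencies = f)$exponent
  b <- fit_spectral_model(10^lp, fit_range = c(5, 30),
                          frequencies = f)$exponent
  expect_equal(a, b, tolerance = 0.1)
})

test_that("aperiodic reconstruction follows the closed form and round-trips", {
  fit <- structure(list(offset = 0, exponent = 1), class = "aperiodic_fit")
  expect_equal(reconstruct_aperiodic(fit, 10), 0.1)
  flat <- structure(list(offset = 0.7, exponent = 0), class = "aperiodic_fit")
  expect_equal(reconstruct_aperiodic(flat, c(2, 17)), rep(10^0.7, 2))
  expect_error(reconstruct_aperiodic(fit, c(1, 0)), "positive")

  f <- seq(1, 30, by = 0.125)
  pl <- 10^(0.8 - 1.4 * log10(f))
  refit <- fit_spectral_model(pl, frequencies = f)
  expect_equal(predict(refit, f), pl, tolerance = 0.01)
  expect_equal(unname(coef(refit)), c(0.8, 1.4), tolerance = 0.01)
})

test_that("exponents are recovered within 0.1 with peaks and 5% noise", {
  f <- seq(1, 30, by = 0.125)
  errs <- vapply(1:6, function(k) {
    beta <- 1 + 0.25 * k
    sp <- synthetic_spectrum(f, offset = 1, exponent = beta,
                             peak_list = list(c(10, 0.5, 1.5), c(20, 0.3, 2)),
                             noise_sd = 0.05, seed = 50 + k)
    fit_spectral_model(sp)$exponent - beta
  }, 0)
  expect_lt(max(abs(errs)), 0.1)
})

test_that("non-positive power in the fit range is an error", {
  f <- seq(1, 30, by = 0.5)
  p <- 10^(1 - log10(f)); p[5] <- 0
  expect_error(fit_spectral_model(p, frequencies = f), "non-positive")
})
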