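test_that("fGn with H = 0.5 is white noise", {
  n <- 8192
  x <- generate_fgn(0.5, n, seed = 11)
  r1 <- cor(x[-1], x[-n])
  expect_lt(abs(r1), 3 / sqrt(n))
  expect_equal(var(x), 1, tolerance = 0.1)
})

test_that("fGn sample autocovariance matches the closed form at small lags", {
  n <- 2^16
  x <- generate_fgn(0.8, n, seed = 7)
  emp <- acf(x, lag.max = 10, plot = FALSE, demean = TRUE)$acf[2:11] * var(x)
  theo <- fgn_acov_oracle(0.8, 1:10)
  # Monte-Carlo error of the lag-k autocovariance at this n is well below 0.05
  expect_equal(as.numeric(emp), theo, tolerance = 0.05)
})

test_that("fGn is reproducible under a fixed seed and rejects bad hurst", {
  a <- generate_fgn(0.7, 4096, seed = 42)
  b <- generate_fgn(0.7, 4096, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, generate_fgn(0.7, 4096, seed = 43)))
  expect_error(generate_fgn(0, 100), "hurst")
  expect_error(generate_fgn(1, 100), "hurst")
  expect_error(generate_fgn(1.3, 100), "hurst")
})
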