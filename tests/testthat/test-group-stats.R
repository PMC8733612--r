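test_that("ANCOVA matches the nested-SSE oracle on random instances", {
  for (k in 1:5) {
    set.seed(60 + k)
    n <- 20
    g <- rep(c("control", "patient"), c(12, 8))
    age <- runif(n, 2, 16)
    y <- rnorm(n) + 0.5 * (g == "patient") + 0.05 * age
    ours <- ancova_group_age(y, g, age)
    oracle <- ancova_oracle(y, as.numeric(g == "patient"), age)
    expect_equal(unname(ours["F"]), unname(oracle["F"]), tolerance = 1e-10)
    expect_equal(unname(ours["p"]), unname(oracle["p"]), tolerance = 1e-10)
  }
})

test_that("ANCOVA handles perfect separation and degenerate outcomes", {
  g <- rep(c("control", "patient"), each = 10)
  age <- runif(20, 1, 15)
  y <- as.numeric(g == "patient")
  expect_lt(ancova_group_age(y, g, age)["p"], 1e-10)
  const <- ancova_group_age(rep(3, 20), g, age)
  expect_equal(unname(const["F"]), 0)
  expect_equal(unname(const["p"]), 1)
  expect_error(ancova_group_age(rnorm(20), g, as.numeric(g == "patient")),
               "collinear")
})

test_that("null per-bin ANCOVA rejects at roughly the nominal rate", {
  set.seed(66)
  n <- 40
  g <- rep(c("control", "patient"), each = n / 2)
  age <- runif(n, 2, 16)
  vals <- matrix(rnorm(n * 300), n, 300)
  res <- spectrum_group_test(vals, g, age, m_bins = 300)
  rate <- mean(res$significant_unc)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
  expect_equal(attr(res, "bonferroni_threshold"), 0.05 / 300)
  expect_lte(sum(res$significant_bonf), 1)
  expect_true(all(res$significant_unc[res$significant_bonf]))
})

test_that("per-bin tests localize an injected low-frequency effect", {
  set.seed(67)
  n <- 50
  g <- rep(c("control", "patient"), c(30, 20))
  age <- runif(n, 2, 16)
  vals <- matrix(rnorm(n * 44), n, 44)
  vals[g == "patient", 1:6] <- vals[g == "patient", 1:6] + 2.5
  res <- spectrum_group_test(vals, g, age, m_bins = 44)
  expect_true(all(res$significant_bonf[1:6]))
  expect_lt(mean(res$significant_unc[10:44]), 0.2)
  rng <- attr(res, "ranges")
  expect_equal(rng[[1]], c(1, 6))
})

test_that("electrode-level tests use the 19-fold Bonferroni family", {
  set.seed(68)
  n <- 30
  g <- rep(c("control", "patient"), each = 15)
  age <- runif(n, 2, 16)
  vals <- matrix(rnorm(n * 19), n, 19) + 2 * (g == "patient")
  res <- electrode_group_test(vals, g, age)
  expect_equal(attr(res, "bonferroni_threshold"), 0.05 / 19)
  expect_true(all(res$significant_bonf))
  null <- electrode_group_test(matrix(rnorm(n * 19), n, 19), g, age)
  expect_lte(sum(null$significant_bonf), 1)
})

test_that("partial correlation matches the residualization oracle", {
  set.seed(69)
  age <- runif(12, 2, 16)
  x <- 0.3 * age + rnorm(12)
  y <- -0.2 * age + 0.6 * x + rnorm(12)
  ours <- partial_correlation_age(x, y, age)
  oracle <- pcor_oracle(x, y, age)
  expect_equal(unname(ours["rho"]), unname(oracle["rho"]), tolerance = 1e-12)
  expect_equal(unname(ours["p"]), unname(oracle["p"]), tolerance = 1e-12)

  exact <- partial_correlation_age(x, x, age)
  expect_equal(unname(exact["rho"]), 1, tolerance = 1e-12)

  x2 <- c(x, NA, NA)
  y2 <- c(y, 1, 2)
  age2 <- c(age, 5, 6)
  expect_equal(unname(partial_correlation_age(x2, y2, age2)["n"]), 12)
  expect_error(partial_correlation_age(x[1:4], y[1:4], age[1:4]), "at least 5")
})

test_that("age slopes recover linear trends and validate inputs", {
  set.seed(70)
  age <- runif(40, 2, 16)
  fit <- age_slope(2 * age + rnorm(40, sd = 1e-6), age)
  expect_equal(unname(fit["slope"]), 2, tolerance = 1e-4)
  expect_lt(fit["p"], 1e-10)
  null <- age_slope(rnorm(40), age)
  expect_lt(abs(null["slope"]), 0.2)
  expect_error(age_slope(rnorm(5), rep(3, 5)), "constant")
})

test_that("subgroup comparisons use the Welch t test", {
  set.seed(71)
  a <- rnorm(29, 0, 1); b <- rnorm(21, 0.8, 2)
  ours <- subgroup_ttest(c(a, b), rep(c("u", "v"), c(29, 21)))
  ref <- t.test(a, b, var.equal = FALSE)
  expect_equal(unname(ours["t"]), unname(ref$statistic), tolerance = 1e-12)
  expect_equal(unname(ours["p"]), ref$p.value, tolerance = 1e-12)
  expect_equal(unname(ours["df"]), unname(ref$parameter), tolerance = 1e-12)
  expect_error(subgroup_ttest(1:5, c("a", rep("b", 4))), ">= 2")
})
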