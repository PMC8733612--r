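# Independent oracles used to validate the package implementations.

# Brute-force DFA: non-overlapping windows, per-window lm() detrending.
# Deliberately naive and independent of the package's fluctuation code.
dfa_brute_force <- function(env, fs, lo, hi, n_scales = 15) {
  prof <- cumsum(env - mean(env))
  scales <- exp(seq(log(lo), log(hi), length.out = n_scales))
  Ls <- unique(pmax(4, round(scales * fs)))
  fl <- vapply(Ls, function(L) {
    nw <- floor(length(prof) / L)
    sds <- vapply(seq_len(nw), function(w) {
      y <- prof[((w - 1) * L + 1):(w * L)]
      t <- seq_len(L)
      sqrt(mean(residuals(lm(y ~ t))^2))
    }, 0)
    mean(sds)
  }, 0)
  unname(coef(lm(log10(fl) ~ log10(Ls / fs)))[2])
}

# Closed-form fGn autocovariance, written independently of the package.
fgn_acov_oracle <- function(h, k) {
  0.5 * (abs(k + 1)^(2 * h) - 2 * abs(k)^(2 * h) + abs(k - 1)^(2 * h))
}

# Nested-model ANCOVA F statistic from two explicit lm() fits.
ancova_oracle <- function(y, group01, age) {
  full <- lm(y ~ group01 + age)
  red <- lm(y ~ age)
  n <- length(y)
  sse_f <- sum(residuals(full)^2)
  sse_r <- sum(residuals(red)^2)
  Fv <- (sse_r - sse_f) / (sse_f / (n - 3))
  c(F = Fv, p = pf(Fv, 1, n - 3, lower.tail = FALSE))
}

# Partial correlation via two explicit residualizations.
pcor_oracle <- function(x, y, age) {
  rx <- residuals(lm(x ~ age))
  ry <- residuals(lm(y ~ age))
  r <- cor(rx, ry)
  n <- length(x)
  tv <- r * sqrt((n - 3) / (1 - r^2))
  c(rho = r, p = 2 * pt(-abs(tv), n - 3))
}

# Fraction of signal variance inside a frequency band, by Welch integration.
band_variance_fraction <- function(x, fs, lo, hi) {
  ps <- welch_psd(x, fs)
  keep <- ps$frequencies > 0
  sel <- ps$frequencies >= lo & ps$frequencies <= hi
  sum(ps$power[1, sel & keep]) / sum(ps$power[1, keep])
}
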