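#' Fractional Gaussian noise by circulant embedding
#'
#' Generates a stationary Gaussian series whose autocovariance is exactly
#' that of fractional Gaussian noise (fGn) with Hurst parameter `hurst`,
#' using the Davies-Harte circulant-embedding construction. fGn is the
#' increment process of fractional Brownian motion: `hurst = 0.5` gives
#' white noise, `hurst > 0.5` gives long-range positive autocorrelations
#' whose DFA exponent equals `hurst`.
#'
#' @param hurst Hurst parameter, strictly between 0 and 1.
#' @param n_samples number of samples (>= 2).
#' @param seed optional integer seed; if given, the series is reproducible.
#' @return Numeric vector of length `n_samples` with unit marginal variance.
#' @examples
#' x <- generate_fgn(0.75, 1024, seed = 1)
#' @export
generate_fgn <- function(hurst, n_samples, seed = NULL) {
  if (!is.numeric(hurst) || length(hurst) != 1 || hurst <= 0 || hurst >= 1) {
    stop("hurst must lie strictly in (0, 1)")
  }
  n <- as.integer(n_samples)
  stopifnot(n >= 2)
  if (!is.null(seed)) set.seed(as.integer(seed))
  lambda <- fgn_eigenvalues(hurst, n)
  m <- length(lambda)
  half <- m / 2
  w <- complex(length.out = m)
  w[1] <- sqrt(lambda[1]) * stats::rnorm(1)
  w[half + 1] <- sqrt(lambda[half + 1]) * stats::rnorm(1)
  a <- stats::rnorm(half - 1)
  b <- stats::rnorm(half - 1)
  idx <- 2:half
  w[idx] <- sqrt(lambda[idx] / 2) * complex(real = a, imaginary = b)
  w[m + 2 - idx] <- Conj(w[idx])
  x <- Re(stats::fft(w)) / sqrt(m)
  x[seq_len(n)]
}

# Eigenvalues of the circulant embedding (size 2n) of the fGn covariance;
# memoized, since cohort generation reuses the same (hurst, n) many times.
.fgn_cache <- new.env(parent = emptyenv())

fgn_eigenvalues <- function(hurst, n) {
  key <- paste(hurst, n, sep = "|")
  hit <- get0(key, envir = .fgn_cache)
  if (!is.null(hit)) return(hit)
  g <- fgn_autocovariance(hurst, n)              # gamma(0..n-1)
  gn <- fgn_autocovariance_at(hurst, n)          # gamma(n)
  row <- c(g, gn, rev(g[-1]))                    # length 2n
  lambda <- Re(stats::fft(row))
  # The fGn embedding is provably nonnegative-definite; clip tiny negative
  # eigenvalues arising from floating-point roundoff.
  lambda[lambda < 0 & lambda > -1e-8 * max(lambda)] <- 0
  if (any(lambda < 0)) stop("circulant embedding produced negative eigenvalues")
  if (length(ls(.fgn_cache)) > 32) rm(list = ls(.fgn_cache), envir = .fgn_cache)
  assign(key, lambda, envir = .fgn_cache)
  lambda
}

# Closed-form fGn autocovariance gamma(k) = 0.5 (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})
# for k = 0..n-1 (unit variance).
fgn_autocovariance <- function(hurst, n) {
  k <- 0:(n - 1)
  fgn_autocovariance_at(hurst, k)
}

fgn_autocovariance_at <- function(hurst, k) {
  h2 <- 2 * hurst
  0.5 * (abs(k + 1)^h2 - 2 * abs(k)^h2 + abs(k - 1)^h2)
}
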