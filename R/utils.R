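# Low-level signal helpers shared across modules.

# Next 5-smooth integer >= n. R's mixed-radix FFT degrades badly on sizes
# with large prime factors; padding convolutions to a 5-smooth length keeps
# long-recording filtering fast.
next_fast_len <- function(n) {
  if (n <= 2) return(2L)
  m <- as.integer(n)
  repeat {
    k <- m
    for (p in c(2L, 3L, 5L)) while (k %% p == 0L) k <- k %/% p
    if (k == 1L) return(m)
    m <- m + 1L
  }
}

#' Analytic signal and amplitude envelope
#'
#' Computes the analytic signal via the frequency-domain Hilbert transform
#' (negative frequencies zeroed, positive doubled) and returns its modulus,
#' i.e. the instantaneous amplitude of the narrowband input.
#'
#' @param x numeric vector, a (narrowband) signal.
#' @return Nonnegative numeric vector of the same length as `x`.
#' @examples
#' t <- seq(0, 1, by = 1/250)
#' env <- amplitude_envelope(3 * sin(2 * pi * 10 * t))
#' @export
amplitude_envelope <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  Mod(analytic_signal(x))
}

analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Hamming-window FIR band-pass design. Order chosen from the transition
# bandwidth by the Hamming rule (approx 3.3 / normalized transition width),
# forced even so the filter has an integer group delay. Designs are
# memoized: the per-bin measure loops request the same kernels repeatedly.
.fir_cache <- new.env(parent = emptyenv())

design_fir_bandpass <- function(low_hz, high_hz, fs, transition_hz = 1) {
  nyq <- fs / 2
  if (!(low_hz > 0 && high_hz > low_hz && high_hz < nyq)) {
    stop("band edges must satisfy 0 < low < high < Nyquist (", nyq, " Hz)")
  }
  key <- paste(low_hz, high_hz, fs, transition_hz, sep = "|")
  hit <- get0(key, envir = .fir_cache)
  if (!is.null(hit)) return(hit)
  ord <- ceiling(3.3 * fs / transition_hz)
  if (ord %% 2 == 1) ord <- ord + 1
  kern <- signal::fir1(ord, c(low_hz, high_hz) / nyq, type = "pass",
                       window = signal::hamming(ord + 1))
  assign(key, kern, envir = .fir_cache)
  kern
}

# Hamming-window FIR low-pass (for anti-alias filtering before decimation).
design_fir_lowpass <- function(cutoff_hz, fs, transition_hz) {
  ord <- ceiling(3.3 * fs / transition_hz)
  if (ord %% 2 == 1) ord <- ord + 1
  signal::fir1(ord, cutoff_hz / (fs / 2), type = "low",
               window = signal::hamming(ord + 1))
}

# Zero-phase FIR application. The linear-phase kernel is applied in the
# frequency domain with its group delay (order/2 samples) compensated by a
# phase rotation, which is numerically identical to centering the kernel at
# lag zero. Linear (not circular) convolution is ensured by zero-padding.
fir_apply_zerophase <- function(x, kernel) {
  n <- length(x)
  k <- length(kernel)
  if (n < 3 * k) stop("signal too short for the filter order (need >= ", 3 * k, " samples)")
  nfft <- next_fast_len(n + k - 1L)
  H <- fir_freqz_zerophase(kernel, nfft)
  X <- stats::fft(c(x, numeric(nfft - n)))
  Re(stats::fft(X * H, inverse = TRUE))[seq_len(n)] / nfft
}

# Real (zero-phase) frequency response of a linear-phase FIR: the DFT of the
# kernel rotated so its symmetry center sits at lag zero.
fir_freqz_zerophase <- function(kernel, nfft) {
  k <- length(kernel)
  d <- (k - 1) / 2
  H <- stats::fft(c(kernel, numeric(nfft - k)))
  w <- 2 * pi * (seq_len(nfft) - 1) / nfft
  Re(H * exp(1i * w * d))
}

# Filtered analytic signal in one pass: multiply the signal spectrum by the
# zero-phase filter response, zero the negative frequencies, inverse FFT.
# Returns the complex analytic signal of the band-passed input; used by the
# per-bin measure loops where the same signal FFT is reused across bins.
filtered_analytic <- function(X, H, n, nfft) {
  h <- numeric(nfft)
  if (nfft %% 2 == 0) {
    h[1] <- 1; h[nfft / 2 + 1] <- 1; h[2:(nfft / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((nfft + 1) / 2)] <- 2
  }
  stats::fft(X * H * h, inverse = TRUE)[seq_len(n)] / nfft
}

# Population SD (divide by n); the convention used by the DFA and fE/I
# window statistics.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

# Linear detrend (least squares) of a vector.
detrend_linear <- function(y) {
  t <- seq_along(y) - (length(y) + 1) / 2
  y - mean(y) - (sum(t * y) / sum(t * t)) * t
}

# Seed expansion: derive a stream of child seeds from one parent seed by a
# counter, keeping everything inside the 32-bit integer range.
derive_seeds <- function(seed, n) {
  stopifnot(length(seed) == 1, is.finite(seed))
  (as.integer(seed) %% 1000003L) * 1009L + 7L * seq_len(n)
}
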