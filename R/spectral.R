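# Welch power spectral density at 0.125-Hz resolution, band aggregation,
# whole-brain averaging.

new_psd_spectrum <- function(power, frequencies, params = list()) {
  structure(list(frequencies = frequencies, power = power, params = params),
            class = "psd_spectrum")
}

#' @export
print.psd_spectrum <- function(x, ...) {
  cat(sprintf("<psd_spectrum> %d channels x %d bins, %.3g-%.4g Hz (df = %g Hz)\n",
              nrow(x$power), length(x$frequencies), min(x$frequencies),
              max(x$frequencies),
              if (length(x$frequencies) > 1) diff(x$frequencies[1:2]) else NA))
  invisible(x)
}

#' @export
plot.psd_spectrum <- function(x, channel = 1, log = "xy", ...) {
  keep <- x$frequencies > 0
  graphics::plot(x$frequencies[keep], x$power[channel, keep], type = "l",
                 log = log, xlab = "Frequency (Hz)",
                 ylab = expression(paste("PSD (", mu, V^2, "/Hz)")), ...)
  invisible(x)
}

#' Welch power spectral density (0.125-Hz grid)
#'
#' Welch's method with 2-s Hamming windows and 50% overlap. The FFT length
#' is `sampling_rate / 0.125` (segments are zero-padded), giving a frequency
#' resolution of 0.125 Hz regardless of sampling rate. Density scaling: the
#' integral of the PSD over frequency approximates the signal variance.
#'
#' When given an `eeg_epochs` object, segments are drawn only from
#' contiguous runs of kept epochs at least one segment long, so no Welch
#' window spans a rejection gap.
#'
#' @param x an `eeg_recording`, `eeg_epochs`, or channels x samples matrix.
#' @param sampling_rate sampling rate in Hz (ignored when `x` carries one).
#' @param segment_s Welch segment length in seconds.
#' @param overlap fractional segment overlap.
#' @return A `psd_spectrum`: frequencies (Hz) and channels x bins power
#'   (uV^2/Hz).
#' @export
welch_psd <- function(x, sampling_rate = NULL, segment_s = 2, overlap = 0.5) {
  runs <- signal_runs(x, sampling_rate)
  fs <- runs$fs
  seg <- round(segment_s * fs)
  nfft_exact <- fs / 0.125
  nfft <- round(nfft_exact)
  if (abs(nfft_exact - nfft) > 1e-9 || nfft %% 2 == 1) {
    nfft <- 2L * round(nfft_exact / 2)
    warning("fs/0.125 is not an even integer; FFT length rounded to ", nfft)
  }
  total <- sum(vapply(runs$runs, ncol, 1L))
  if (total < seg) stop("need at least ", segment_s, " s of signal")
  win <- as.numeric(signal::hamming(seg))
  U <- sum(win^2)
  step <- max(1L, round(seg * (1 - overlap)))
  nch <- nrow(runs$runs[[1]])
  acc <- matrix(0, nch, nfft %/% 2 + 1)
  nseg <- 0L
  for (run in runs$runs) {
    nr <- ncol(run)
    if (nr < seg) next
    starts <- seq(1L, nr - seg + 1L, by = step)
    for (s in starts) {
      segm <- run[, s:(s + seg - 1L), drop = FALSE] * rep(win, each = nch)
      X <- stats::mvfft(t(cbind(segm, matrix(0, nch, nfft - seg))))
      acc <- acc + t(Mod(X[1:(nfft %/% 2 + 1), , drop = FALSE])^2)
      nseg <- nseg + 1L
    }
  }
  if (nseg == 0L) stop("no run long enough for a single Welch segment")
  p <- acc / nseg * (2 / (fs * U))
  p[, 1] <- p[, 1] / 2
  p[, ncol(p)] <- p[, ncol(p)] / 2
  freqs <- (0:(nfft %/% 2)) * fs / nfft
  rownames(p) <- rownames(runs$runs[[1]])
  new_psd_spectrum(p, freqs,
                   params = list(segment_s = segment_s, overlap = overlap,
                                 window = "hamming", nfft = nfft,
                                 n_segments = nseg, sampling_rate = fs))
}

# Normalize the welch/measure input into a list of contiguous channel x
# sample runs plus the sampling rate.
signal_runs <- function(x, sampling_rate = NULL) {
  if (inherits(x, "eeg_recording")) {
    list(runs = list(x$signal), fs = x$sampling_rate)
  } else if (inherits(x, "eeg_epochs")) {
    list(runs = epoch_runs(x), fs = x$sampling_rate)
  } else {
    if (is.null(sampling_rate)) stop("sampling_rate required for a bare matrix")
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    list(runs = list(x), fs = sampling_rate)
  }
}

#' Mean band power per channel
#'
#' Average of the PSD over all frequency bins with
#' `low_hz <= f <= high_hz` (inclusive). Off-grid edges printed at reduced
#' precision (e.g. 4.63 Hz on the 0.125-Hz grid) are snapped to the nearest
#' grid point.
#'
#' @param spectrum a `psd_spectrum`.
#' @param low_hz,high_hz band edges in Hz.
#' @return Named numeric vector, one mean power per channel.
#' @export
band_average_power <- function(spectrum, low_hz, high_hz) {
  stopifnot(inherits(spectrum, "psd_spectrum"))
  f <- spectrum$frequencies
  df <- if (length(f) > 1) diff(f[1:2]) else 1
  lo <- snap_to_grid(low_hz, f, df)
  hi <- snap_to_grid(high_hz, f, df)
  sel <- f >= lo - 1e-9 & f <= hi + 1e-9
  if (!any(sel)) stop("no frequency bins inside [", low_hz, ", ", high_hz, "] Hz")
  rowMeans(spectrum$power[, sel, drop = FALSE])
}

snap_to_grid <- function(edge, f, df) {
  g <- f[which.min(abs(f - edge))]
  if (abs(g - edge) <= df / 2) g else edge
}

#' Whole-brain average of per-electrode values
#'
#' Arithmetic mean across electrodes.
#'
#' @param values numeric vector (one value per electrode) or matrix
#'   (electrodes x bins).
#' @return Scalar, or one mean per bin for matrix input.
#' @export
whole_brain_average <- function(values) {
  if (is.matrix(values)) colMeans(values) else mean(values)
}
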