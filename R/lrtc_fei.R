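# Long-range temporal correlations (DFA of narrowband amplitude envelopes)
# and the functional excitation/inhibition ratio (fE/I), per electrode in
# 1-Hz bins.

#' Narrowband FIR filter for 1-Hz analysis bins
#'
#' Hamming-windowed FIR band-pass `[bin_start_hz, bin_start_hz + width]` Hz
#' with 1-Hz transition bands, applied zero-phase.
#'
#' @param x numeric vector, one channel.
#' @param bin_start_hz lower edge of the bin (Hz).
#' @param sampling_rate sampling rate (Hz).
#' @param width bin width in Hz.
#' @return Filtered signal, same length as `x`.
#' @export
narrowband_filter <- function(x, bin_start_hz, sampling_rate, width = 1) {
  kern <- design_fir_bandpass(bin_start_hz, bin_start_hz + width,
                              sampling_rate, transition_hz = 1)
  fir_apply_zerophase(x, kern)
}

#' DFA exponent of an amplitude envelope
#'
#' Detrended fluctuation analysis: the envelope is demeaned and integrated
#' into a cumulative-sum profile; for each of `n_scales` logarithmically
#' spaced window sizes the profile is split into 50%-overlapping windows,
#' each window's linear trend removed, and the fluctuation taken as the mean
#' across windows of the per-window SD. The DFA exponent is the least-squares
#' slope of log10 fluctuation against log10 scale. An exponent of 0.5
#' indicates an uncorrelated signal; values in (0.5, 1) indicate long-range
#' temporal correlations.
#'
#' @param envelope numeric vector, amplitude envelope (or any series whose
#'   scaling is of interest).
#' @param sampling_rate sampling rate (Hz).
#' @param scale_range_s length-2 numeric, smallest and largest window in
#'   seconds (2-20 s for analysis bins at and above 8 Hz, 4-20 s below).
#' @param overlap fractional window overlap.
#' @param n_scales number of logarithmically spaced scales.
#' @return A `dfa_fit` object: `exponent`, `scales` (s), `fluctuations`,
#'   `fit_r2`.
#' @examples
#' fit <- dfa_exponent(abs(rnorm(5000)), 250, scale_range_s = c(0.1, 2))
#' @export
dfa_exponent <- function(envelope, sampling_rate, scale_range_s = c(2, 20),
                         overlap = 0.5, n_scales = 15) {
  res <- dfa_from_runs(list(envelope), sampling_rate, scale_range_s,
                       overlap, n_scales)
  res
}

dfa_from_runs <- function(env_list, fs, scale_range_s, overlap = 0.5,
                          n_scales = 15) {
  stopifnot(scale_range_s[2] > scale_range_s[1], scale_range_s[1] > 0)
  total <- sum(lengths(env_list))
  if (total < 5 * scale_range_s[2] * fs) {
    stop("envelope too short: need >= 5 x the largest scale (",
         5 * scale_range_s[2], " s)")
  }
  if (all(vapply(env_list, function(e) stats::var(e) == 0, TRUE))) {
    stop("degenerate envelope (zero variance)")
  }
  scales <- exp(seq(log(scale_range_s[1]), log(scale_range_s[2]),
                    length.out = n_scales))
  winlens <- unique(pmax(4L, as.integer(round(scales * fs))))
  fl <- rep(0, length(winlens))
  nw <- rep(0L, length(winlens))
  for (env in env_list) {
    if (length(env) < min(winlens)) next
    profile <- cumsum(env - mean(env))
    r <- dfa_fluct_cpp(profile, winlens, overlap)
    ok <- !is.na(r$fluct)
    fl[ok] <- fl[ok] + r$fluct[ok] * r$nwin[ok]
    nw[ok] <- nw[ok] + r$nwin[ok]
  }
  keep <- nw > 0 & fl > 0
  if (sum(keep) < 3) stop("not enough valid scales for a DFA fit")
  fluct <- fl[keep] / nw[keep]
  sc <- winlens[keep] / fs
  fit <- stats::lm.fit(cbind(1, log10(sc)), log10(fluct))
  r2 <- 1 - sum(fit$residuals^2) / sum((log10(fluct) - mean(log10(fluct)))^2)
  structure(list(exponent = unname(fit$coefficients[2]), scales = sc,
                 fluctuations = fluct, fit_r2 = r2,
                 scale_range_s = scale_range_s, n_windows = nw[keep]),
            class = "dfa_fit")
}

#' @export
print.dfa_fit <- function(x, ...) {
  cat(sprintf("<dfa_fit> exponent = %.3f (r2 = %.4f), %d scales in %g-%g s\n",
              x$exponent, x$fit_r2, length(x$scales),
              x$scale_range_s[1], x$scale_range_s[2]))
  invisible(x)
}

#' @export
plot.dfa_fit <- function(x, ...) {
  graphics::plot(x$scales, x$fluctuations, log = "xy",
                 xlab = "Scale (s)", ylab = "Fluctuation", ...)
  graphics::abline(stats::lm(log10(x$fluctuations) ~ log10(x$scales)),
                   untf = FALSE, col = "grey50")
  invisible(x)
}

#' Functional excitation/inhibition ratio (fE/I) of a narrowband signal
#'
#' The signal's amplitude envelope is split into 5-s windows with 80%
#' overlap. Per window, `wAmp` is the mean envelope and `wDNF` the SD of the
#' linearly detrended cumulative sum of the window's envelope normalized by
#' `wAmp` (an amplitude-normalized fluctuation that approximates the DFA
#' exponent's local fluctuation). fE/I is 1 minus the Pearson correlation of
#' `wAmp` and `wDNF` across windows: values below 1 indicate
#' inhibition-dominated dynamics (positive amplitude-fluctuation coupling),
#' above 1 excitation-dominated, close to 1 balanced.
#'
#' The result is flagged invalid when the DFA exponent in the same band does
#' not exceed `validity_threshold` (the estimator is uninformative without
#' long-range temporal correlations) or when either window statistic has
#' zero variance.
#'
#' @param x numeric vector: a narrowband signal (the envelope is computed
#'   internally).
#' @param sampling_rate sampling rate (Hz).
#' @param window_s window length in seconds.
#' @param overlap fractional window overlap.
#' @param scale_range_s DFA scale range used for the companion exponent.
#' @param validity_threshold DFA exponent below which the result is flagged
#'   invalid; set `apply_validity = FALSE` to skip the rule (the flag is
#'   still reported).
#' @param apply_validity logical; apply the DFA validity rule.
#' @param min_windows minimum number of windows required.
#' @return A `fei_result`: `fei`, `window_amplitudes`,
#'   `window_fluctuations`, `dfa_in_bin`, `valid`.
#' @export
fei_value <- function(x, sampling_rate, window_s = 5, overlap = 0.8,
                      scale_range_s = c(2, 20), validity_threshold = 0.6,
                      apply_validity = TRUE, min_windows = 20) {
  env <- amplitude_envelope(x)
  fei_from_runs(list(env), sampling_rate, window_s, overlap, scale_range_s,
                validity_threshold, apply_validity, min_windows)
}

fei_from_runs <- function(env_list, fs, window_s = 5, overlap = 0.8,
                          scale_range_s = c(2, 20), validity_threshold = 0.6,
                          apply_validity = TRUE, min_windows = 20,
                          dfa_precomputed = NULL) {
  L <- as.integer(round(window_s * fs))
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  wamp <- numeric(0)
  wdnf <- numeric(0)
  for (env in env_list) {
    if (length(env) < L) next
    w <- fei_windows_cpp(env, L, step)
    wamp <- c(wamp, w$wamp)
    wdnf <- c(wdnf, w$wdnf)
  }
  if (length(wamp) < min_windows) {
    stop("need at least ", min_windows, " analysis windows (",
         min_windows * window_s * (1 - overlap) + window_s * overlap, " s)")
  }
  dfa <- if (!is.null(dfa_precomputed)) {
    dfa_precomputed
  } else {
    tryCatch(dfa_from_runs(env_list, fs, scale_range_s)$exponent,
             error = function(e) NA_real_)
  }
  ok <- is.finite(wamp) & is.finite(wdnf)
  degenerate <- sum(ok) < min_windows ||
    stats::var(wamp[ok]) == 0 || stats::var(wdnf[ok]) == 0
  fei <- if (degenerate) NA_real_ else 1 - stats::cor(wamp[ok], wdnf[ok])
  valid <- !degenerate &&
    (!apply_validity || (is.finite(dfa) && dfa > validity_threshold))
  structure(list(fei = fei, window_amplitudes = wamp,
                 window_fluctuations = wdnf, dfa_in_bin = dfa,
                 valid = valid, validity_threshold = validity_threshold,
                 window_s = window_s, overlap = overlap),
            class = "fei_result")
}

#' @export
print.fei_result <- function(x, ...) {
  cat(sprintf("<fei_result> fE/I = %.3f (%s), DFA in bin = %.3f, %d windows\n",
              x$fei, if (isTRUE(x$valid)) "valid" else "flagged invalid",
              x$dfa_in_bin, length(x$window_amplitudes)))
  invisible(x)
}

# Scale-range rule: analysis bins starting at or above 8 Hz use 2-20 s,
# lower bins 4-20 s (short scales are biased by the narrowband filter's
# impulse response at low frequencies).
dfa_scale_range <- function(bin_start_hz) {
  if (bin_start_hz >= 8) c(2, 20) else c(4, 20)
}

#' Per-electrode, per-frequency-bin biomarker spectrum
#'
#' Computes DFA exponents or fE/I values for every electrode in 1-Hz
#' analysis bins spanning 1-45 Hz (bin start frequencies 1..44). Each bin is
#' extracted with a Hamming-windowed FIR filter (1-Hz transition bands,
#' zero-phase); the Hilbert amplitude envelope feeds the requested
#' estimator. DFA scale ranges follow the bin rule (2-20 s at and above
#' 8 Hz, 4-20 s below). With epoched input, estimation windows never span a
#' rejection gap.
#'
#' @param x an `eeg_recording`, `eeg_epochs`, or channels x samples matrix.
#' @param measure `"dfa"` or `"fei"`.
#' @param sampling_rate required for matrix input.
#' @param bins integer vector of bin start frequencies (default 1..44).
#' @param min_length_s minimum total clean signal length; recordings shorter
#'   than this are rejected (inclusion criterion).
#' @param fei_validity_threshold,fei_apply_validity fE/I validity rule
#'   controls (see [fei_value()]).
#' @return A `measure_spectrum` object: `values` (electrodes x bins),
#'   `validity` (same shape), `bins`, `measure`.
#' @export
measure_spectrum <- function(x, measure = c("dfa", "fei"),
                             sampling_rate = NULL, bins = 1:44,
                             min_length_s = 100,
                             fei_validity_threshold = 0.6,
                             fei_apply_validity = TRUE) {
  measure <- match.arg(measure)
  runs <- signal_runs(x, sampling_rate)
  fs <- runs$fs
  total_s <- sum(vapply(runs$runs, ncol, 1L)) / fs
  if (total_s < min_length_s) {
    stop(sprintf("clean signal length %.1f s is below the %g s minimum",
                 total_s, min_length_s))
  }
  core <- measure_core(runs$runs, fs, bins, want = measure,
                       fei_validity_threshold = fei_validity_threshold,
                       fei_apply_validity = fei_apply_validity)
  structure(list(measure = measure, bins = bins, values = core[[measure]],
                 validity = core$validity[[measure]], sampling_rate = fs),
            class = "measure_spectrum")
}

# Shared per-electrode, per-bin engine. Each channel's FFT and each bin's
# zero-phase filter response are computed once; the band-limited analytic
# signal then feeds the DFA exponent and/or the fE/I statistic from the
# same envelope. When both measures are requested the DFA exponent doubles
# as fE/I's in-bin validity reference.
measure_core <- function(run_list, fs, bins, want = c("dfa", "fei"),
                         fei_validity_threshold = 0.6,
                         fei_apply_validity = TRUE) {
  nch <- nrow(run_list[[1]])
  labs <- rownames(run_list[[1]]) %||% paste0("ch", seq_len(nch))
  blank <- matrix(NA_real_, nch, length(bins), dimnames = list(labs, bins))
  vals <- list(dfa = blank, fei = blank)
  valid <- list(dfa = blank == 1, fei = blank == 1)
  kerns <- lapply(bins, function(f)
    design_fir_bandpass(f, f + 1, fs, transition_hz = 1))
  klen <- max(lengths(kerns))
  nffts <- vapply(run_list, function(r) next_fast_len(ncol(r) + klen - 1L), 1L)
  H <- lapply(seq_along(run_list), function(ri)
    lapply(kerns, fir_freqz_zerophase, nfft = nffts[ri]))
  need_dfa <- "dfa" %in% want
  need_fei <- "fei" %in% want
  for (ch in seq_len(nch)) {
    X <- lapply(seq_along(run_list), function(ri) {
      r <- run_list[[ri]]
      stats::fft(c(r[ch, ], numeric(nffts[ri] - ncol(r))))
    })
    for (bi in seq_along(bins)) {
      envs <- lapply(seq_along(X), function(ri) {
        n <- ncol(run_list[[ri]])
        Mod(filtered_analytic(X[[ri]], H[[ri]][[bi]], n, nffts[ri]))
      })
      sr <- dfa_scale_range(bins[bi])
      dfa_val <- NA_real_
      if (need_dfa || (need_fei && fei_apply_validity)) {
        fit <- tryCatch(dfa_from_runs(envs, fs, sr), error = function(e) NULL)
        if (!is.null(fit)) dfa_val <- fit$exponent
      }
      if (need_dfa && is.finite(dfa_val)) {
        vals$dfa[ch, bi] <- dfa_val
        valid$dfa[ch, bi] <- TRUE
      }
      if (need_fei) {
        res <- tryCatch(
          fei_from_runs(envs, fs, scale_range_s = sr,
                        validity_threshold = fei_validity_threshold,
                        apply_validity = FALSE, dfa_precomputed = dfa_val),
          error = function(e) NULL)
        if (!is.null(res)) {
          vals$fei[ch, bi] <- res$fei
          valid$fei[ch, bi] <- !is.na(res$fei) &&
            (!fei_apply_validity ||
               (is.finite(dfa_val) && dfa_val > fei_validity_threshold))
        }
      }
    }
  }
  list(dfa = vals$dfa, fei = vals$fei, validity = valid)
}

#' @export
print.measure_spectrum <- function(x, ...) {
  cat(sprintf("<measure_spectrum> %s: %d electrodes x %d bins (%g-%g Hz), %.0f%% valid\n",
              x$measure, nrow(x$values), length(x$bins), min(x$bins),
              max(x$bins) + 1, 100 * mean(x$validity)))
  invisible(x)
}

#' Band summary of a measure spectrum
#'
#' Mean of per-bin values over all analysis bins fully inside
#' `[low_hz, high_hz]`, per electrode (e.g. DFA over 11-18 Hz, fE/I over
#' 12-24 Hz).
#'
#' @param ms a `measure_spectrum`.
#' @param low_hz,high_hz band edges (Hz).
#' @param valid_only if `TRUE`, average only bins whose validity flag is
#'   set.
#' @return Named numeric vector, one summary per electrode.
#' @export
band_summary <- function(ms, low_hz, high_hz, valid_only = FALSE) {
  stopifnot(inherits(ms, "measure_spectrum"))
  sel <- ms$bins >= low_hz & (ms$bins + 1) <= high_hz
  if (!any(sel)) stop("no analysis bins inside the requested band")
  v <- ms$values[, sel, drop = FALSE]
  if (valid_only) v[!ms$validity[, sel, drop = FALSE]] <- NA
  rowMeans(v, na.rm = TRUE)
}
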