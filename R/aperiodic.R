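# Aperiodic (1/f^beta) spectral parameterization: iterative decomposition
# of a log-power spectrum into an aperiodic line plus Gaussian peaks.

#' Default spectral-model settings
#'
#' Peak widths are constrained to 1-6 Hz, at most 6 peaks, minimum peak
#' height 0.05 log10 units, relative peak threshold 1.5 SD, fixed (no-knee)
#' aperiodic mode.
#'
#' @return Named list of settings for [fit_spectral_model()].
#' @export
spectral_model_settings <- function() {
  list(peak_width_limits = c(1, 6), max_n_peaks = 6, min_peak_height = 0.05,
       peak_threshold = 1.5, aperiodic_mode = "fixed")
}

#' Fit the aperiodic-plus-peaks spectral model
#'
#' Decomposes each channel's power spectrum (in log10 power vs log10
#' frequency) into an aperiodic component `offset - exponent * log10(f)`
#' plus up to `max_n_peaks` Gaussian peaks. The procedure: (1) robust
#' initial line fit (points above the 97.5th percentile of residuals are
#' discarded and the line refit); (2) peaks are extracted iteratively from
#' the residual, largest first, while the maximum exceeds both
#' `min_peak_height` and `peak_threshold` x residual SD; (3) all Gaussians
#' are refit jointly by bounded least squares; (4) the aperiodic line is
#' refit on the peak-removed spectrum. Goodness of fit is the R^2 between
#' the full model and the log10 spectrum.
#'
#' @param spectrum a `psd_spectrum` (all channels are fit) or a numeric
#'   vector of power values with `frequencies` supplied.
#' @param fit_range length-2 numeric, frequency range of the fit (Hz).
#' @param settings list as produced by [spectral_model_settings()].
#' @param frequencies frequency grid when `spectrum` is a bare vector.
#' @return For multi-channel input, a list of `aperiodic_fit` objects (one
#'   per channel); for single-channel input, one `aperiodic_fit` with
#'   fields `offset`, `exponent`, `peaks`, `r2`, `fit_range`.
#' @export
fit_spectral_model <- function(spectrum, fit_range = c(1, 30),
                               settings = spectral_model_settings(),
                               frequencies = NULL) {
  if (inherits(spectrum, "psd_spectrum")) {
    f <- spectrum$frequencies
    pw <- spectrum$power
  } else {
    if (is.null(frequencies)) stop("frequencies required for bare power input")
    f <- frequencies
    pw <- matrix(spectrum, nrow = 1)
  }
  def <- spectral_model_settings()
  def[names(settings)] <- settings
  settings <- def
  sel <- f >= fit_range[1] - 1e-9 & f <= fit_range[2] + 1e-9 & f > 0
  if (sum(sel) < 8) stop("too few frequency bins in the fit range")
  fits <- lapply(seq_len(nrow(pw)), function(ch) {
    p <- pw[ch, sel]
    if (any(p <= 0)) stop("non-positive power inside the fit range")
    fit_one_spectrum(f[sel], p, fit_range, settings)
  })
  names(fits) <- rownames(pw)
  if (length(fits) == 1) fits[[1]] else fits
}

fit_one_spectrum <- function(f, p, fit_range, s) {
  lf <- log10(f)
  lp <- log10(p)
  ap <- robust_line_fit(lf, lp)
  resid <- lp - (ap[1] + ap[2] * lf)
  guesses <- list()
  for (k in seq_len(s$max_n_peaks)) {
    i <- which.max(resid)
    h <- resid[i]
    if (h < s$min_peak_height || h < s$peak_threshold * stats::sd(resid)) break
    ctr <- f[i]
    std <- guess_peak_std(f, resid, i, h, s$peak_width_limits)
    g <- h * exp(-(f - ctr)^2 / (2 * std^2))
    resid <- resid - g
    guesses[[length(guesses) + 1]] <- c(center = ctr, height = h, std = std)
  }
  peaks <- prune_peaks(guesses, fit_range)
  if (length(peaks) > 0) {
    peaks <- refit_peaks_joint(f, lp - (ap[1] + ap[2] * lf), peaks, fit_range,
                               s$peak_width_limits)
    peaks <- prune_peaks(peaks, fit_range)
  }
  peak_model <- peaks_eval(f, peaks)
  ap2 <- stats::lm.fit(cbind(1, lf), lp - peak_model)$coefficients
  model <- ap2[1] + ap2[2] * lf + peak_model
  r2 <- 1 - sum((lp - model)^2) / sum((lp - mean(lp))^2)
  structure(list(offset = unname(ap2[1]), exponent = unname(-ap2[2]),
                 peaks = peaks, r2 = r2, fit_range = fit_range,
                 frequencies = f, log_power = lp, model = model),
            class = "aperiodic_fit")
}

# OLS line fit, then refit after discarding points whose residuals lie
# above the 97.5th percentile (large oscillatory peaks bias the first pass
# upward).
robust_line_fit <- function(lf, lp) {
  co <- stats::lm.fit(cbind(1, lf), lp)$coefficients
  r <- lp - (co[1] + co[2] * lf)
  keep <- r <= stats::quantile(r, 0.975)
  stats::lm.fit(cbind(1, lf[keep]), lp[keep])$coefficients
}

# Peak std from the half-height span of the residual around the maximum,
# bounded by half the allowed full widths.
guess_peak_std <- function(f, resid, i, h, width_limits) {
  half <- h / 2
  lo <- i
  while (lo > 1 && resid[lo] > half) lo <- lo - 1
  hi <- i
  while (hi < length(resid) && resid[hi] > half) hi <- hi + 1
  fwhm <- f[hi] - f[lo]
  std <- fwhm / 2.355
  min(max(std, width_limits[1] / 2), width_limits[2] / 2)
}

# Drop peaks whose center sits within one std of the fit-range edge, and
# merge overlapping peaks (centers closer than 0.75 x std of the wider),
# keeping the taller.
prune_peaks <- function(peaks, fit_range) {
  if (length(peaks) == 0) return(peaks)
  keep <- vapply(peaks, function(p)
    p["center"] - p["std"] > fit_range[1] &&
      p["center"] + p["std"] < fit_range[2], TRUE)
  peaks <- peaks[keep]
  if (length(peaks) < 2) return(peaks)
  drop <- rep(FALSE, length(peaks))
  for (a in seq_along(peaks)) {
    for (b in seq_along(peaks)) {
      if (a >= b || drop[a] || drop[b]) next
      gap <- abs(peaks[[a]]["center"] - peaks[[b]]["center"])
      if (gap < 0.75 * max(peaks[[a]]["std"], peaks[[b]]["std"])) {
        if (peaks[[a]]["height"] >= peaks[[b]]["height"]) drop[b] <- TRUE
        else drop[a] <- TRUE
      }
    }
  }
  peaks[!drop]
}

peaks_eval <- function(f, peaks) {
  out <- numeric(length(f))
  for (p in peaks) {
    out <- out + p["height"] * exp(-(f - p["center"])^2 / (2 * p["std"]^2))
  }
  out
}

# Joint bounded nonlinear least squares over all Gaussian parameters.
refit_peaks_joint <- function(f, resid0, peaks, fit_range, width_limits) {
  npk <- length(peaks)
  par0 <- unlist(peaks)
  lower <- rep(c(fit_range[1], 0, width_limits[1] / 2), npk)
  upper <- rep(c(fit_range[2], Inf, width_limits[2] / 2), npk)
  fn <- function(par) {
    m <- numeric(length(f))
    for (j in seq_len(npk)) {
      c0 <- par[3 * j - 2]; h0 <- par[3 * j - 1]; s0 <- par[3 * j]
      m <- m + h0 * exp(-(f - c0)^2 / (2 * s0^2))
    }
    resid0 - m
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par0, lower = lower, upper = upper, fn = fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-8, ptol = 1e-8)),
    error = function(e) NULL)
  if (is.null(fit)) return(peaks)
  par <- fit$par
  lapply(seq_len(npk), function(j)
    c(center = par[[3 * j - 2]], height = par[[3 * j - 1]], std = par[[3 * j]]))
}

#' @export
print.aperiodic_fit <- function(x, ...) {
  cat(sprintf("<aperiodic_fit> offset = %.3f, exponent = %.3f, %d peak(s), r2 = %.4f (%g-%g Hz)\n",
              x$offset, x$exponent, length(x$peaks), x$r2,
              x$fit_range[1], x$fit_range[2]))
  for (p in x$peaks) {
    cat(sprintf("  peak: %.2f Hz, height %.3f, std %.2f Hz\n",
                p["center"], p["height"], p["std"]))
  }
  invisible(x)
}

#' @export
coef.aperiodic_fit <- function(object, ...) {
  c(offset = object$offset, exponent = object$exponent)
}

#' @export
predict.aperiodic_fit <- function(object, frequencies = NULL, ...) {
  if (is.null(frequencies)) frequencies <- object$frequencies
  reconstruct_aperiodic(object, frequencies)
}

#' @export
plot.aperiodic_fit <- function(x, ...) {
  graphics::plot(log10(x$frequencies), x$log_power, type = "l",
                 xlab = "log10 frequency (Hz)", ylab = "log10 power", ...)
  graphics::lines(log10(x$frequencies), x$model, col = "tomato")
  graphics::lines(log10(x$frequencies),
                  x$offset - x$exponent * log10(x$frequencies),
                  col = "steelblue", lty = 2)
  invisible(x)
}

#' Reconstruct the aperiodic-only spectrum
#'
#' Evaluates `10^(offset - exponent * log10(f))` on the requested grid: the
#' spectrum with all oscillatory peaks removed.
#'
#' @param fit an `aperiodic_fit`.
#' @param frequencies frequency grid (Hz, > 0).
#' @return Power values on the grid.
#' @export
reconstruct_aperiodic <- function(fit, frequencies) {
  stopifnot(inherits(fit, "aperiodic_fit"))
  if (any(frequencies <= 0)) stop("frequencies must be positive")
  10^(fit$offset - fit$exponent * log10(frequencies))
}
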