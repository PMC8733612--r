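# Synthetic EEG generator: narrowband oscillations with log-normal fGn
# amplitude envelopes (tunable DFA exponent), controllable coupling between
# window amplitude and normalized fluctuation (tunable fE/I), 1/f^beta
# aperiodic background with optional spectral peaks, artifact injection and
# cohort assembly with ground-truth bookkeeping.

#' Specification of one synthetic EEG signal
#'
#' Collects every tunable property of a single-channel synthetic signal:
#' the oscillation band and its envelope Hurst exponent, the target
#' amplitude-fluctuation coupling, and the aperiodic background.
#'
#' @param duration duration in seconds (> 0; >= 100 s is required when the
#'   signal feeds DFA or fE/I estimation).
#' @param sampling_rate sampling rate in Hz (>= 2 x the upper band edge).
#' @param band length-2 numeric, oscillation band (Hz), or `NULL` for a
#'   background-only signal.
#' @param hurst target DFA exponent of the oscillation amplitude envelope,
#'   in (0, 1).
#' @param coupling_rho target Pearson correlation between 5-s window
#'   amplitude and normalized detrended fluctuation, in [-1, 1]; positive
#'   values push fE/I below 1 (inhibition-dominated direction).
#' @param aperiodic_beta exponent of the 1/f^beta background (>= 0).
#' @param aperiodic_offset background offset, log10(uV^2/Hz) at 1 Hz.
#' @param peak_list list of numeric triples `c(center_hz, height_log10,
#'   width_hz)` added to the background spectrum in log10 space.
#' @param osc_amplitude RMS amplitude of the oscillation component (uV).
#' @param env_log_sd log-SD of the log-normal envelope; controls envelope
#'   modulation depth.
#' @param seed integer seed making the signal reproducible.
#' @return An object of class `signal_spec`.
#' @export
signal_spec <- function(duration, sampling_rate, band = c(8, 13),
                        hurst = 0.6, coupling_rho = 0,
                        aperiodic_beta = 1.5, aperiodic_offset = 0.8,
                        peak_list = list(), osc_amplitude = 8,
                        env_log_sd = 1, seed = 1) {
  stopifnot(is.numeric(duration), length(duration) == 1)
  if (duration <= 0) stop("duration must be positive")
  if (hurst <= 0 || hurst >= 1) stop("hurst must lie strictly in (0, 1)")
  if (abs(coupling_rho) > 1) stop("coupling_rho must lie in [-1, 1]")
  if (aperiodic_beta < 0) stop("aperiodic_beta must be >= 0")
  if (!is.null(band)) {
    stopifnot(length(band) == 2)
    if (!(band[1] > 0 && band[2] > band[1] && band[2] < sampling_rate / 2)) {
      stop("band must lie strictly inside (0, Nyquist)")
    }
  }
  structure(list(duration = duration, sampling_rate = sampling_rate,
                 band = band, hurst = hurst, coupling_rho = coupling_rho,
                 aperiodic_beta = aperiodic_beta,
                 aperiodic_offset = aperiodic_offset,
                 peak_list = peak_list, osc_amplitude = osc_amplitude,
                 env_log_sd = env_log_sd, seed = as.integer(seed)),
            class = "signal_spec")
}

# 1/f^beta Gaussian background (plus optional log-Gaussian peaks) by direct
# frequency-domain synthesis: each positive-frequency Fourier coefficient is
# complex Gaussian with expected squared modulus S(f) * fs * n / 2, so the
# one-sided periodogram density matches the requested spectrum.
synth_background <- function(n, fs, offset, beta, peak_list = list()) {
  half <- floor(n / 2)
  f <- (1:half) * fs / n
  logS <- offset - beta * log10(f)
  for (p in peak_list) {
    logS <- logS + p[2] * exp(-(f - p[1])^2 / (2 * p[3]^2))
  }
  S <- 10^logS
  amp <- sqrt(S * fs * n / 2)
  X <- complex(length.out = n)
  even <- n %% 2 == 0
  nfree <- if (even) half - 1 else half
  re <- stats::rnorm(nfree)
  im <- stats::rnorm(nfree)
  idx <- 2:(nfree + 1)
  X[idx] <- amp[1:nfree] * complex(real = re, imaginary = im) / sqrt(2)
  if (even) X[half + 1] <- amp[half] * stats::rnorm(1)
  X[n + 2 - idx] <- Conj(X[idx])
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Generate a narrowband oscillation over a 1/f background
#'
#' The oscillation is narrowband-filtered white noise (a stochastic carrier
#' with realistic instantaneous-phase statistics) multiplied by a strictly
#' positive log-normal envelope `exp(s * z)` where `z` is fractional
#' Gaussian noise with the requested Hurst exponent; the envelope therefore
#' carries long-range temporal correlations whose DFA exponent approximates
#' `spec$hurst`. The background is 1/f^beta Gaussian noise with optional
#' spectral peaks.
#'
#' @param spec a [signal_spec()].
#' @param shape carrier spectral shape: `"fir"` (Hamming band-pass edges) or
#'   `"gaussian"` (Gaussian spectral hump covering the band at +/- 2 SD).
#' @param confine if `TRUE`, the modulation sidebands that amplitude
#'   modulation spreads outside the band are stripped, keeping the
#'   component's spectral footprint local.
#' @return Numeric vector of length `duration * sampling_rate` (microvolts).
#' @examples
#' x <- generate_band_signal(signal_spec(30, 250, band = c(8, 13), hurst = 0.7))
#' @export
generate_band_signal <- function(spec, shape = c("fir", "gaussian"),
                                 confine = FALSE) {
  stopifnot(inherits(spec, "signal_spec"))
  shape <- match.arg(shape)
  n <- round(spec$duration * spec$sampling_rate)
  if (n < 2) stop("duration too short at this sampling rate")
  set.seed(spec$seed)
  x <- synth_background(n, spec$sampling_rate, spec$aperiodic_offset,
                        spec$aperiodic_beta, spec$peak_list)
  if (!is.null(spec$band)) {
    x <- x + synth_oscillation(spec, n, shape = shape, confine = confine)
  }
  x
}

synth_oscillation <- function(spec, n, shape = c("fir", "gaussian"),
                              confine = FALSE) {
  shape <- match.arg(shape)
  z <- generate_fgn(spec$hurst, n)
  env <- exp(spec$env_log_sd * z)
  # the carrier is normalized to unit instantaneous amplitude: the phase
  # keeps the statistics of narrowband noise while the signal's envelope
  # becomes exactly the log-normal fGn process, so the injected Hurst
  # exponent is what the envelope carries
  carrier <- synth_carrier_norm(spec, n, shape)
  osc <- carrier * env
  if (confine) osc <- confine_to_band(osc, spec)
  spec$osc_amplitude * osc / sqrt(mean(osc^2))
}

# Strip the broadband sidebands that amplitude modulation spreads outside
# the oscillation band, so the component's spectral footprint stays local;
# modulations slower than the window bandwidth survive. A Gaussian spectral
# window (slightly wider than the carrier's) is used so the component's
# spectrum keeps soft Gaussian tails rather than filter cliffs.
confine_to_band <- function(osc, spec) {
  fs <- spec$sampling_rate
  n <- length(osc)
  fc <- mean(spec$band)
  sfc <- 1.5 * diff(spec$band) / 4
  half <- floor(n / 2)
  f <- (1:half) * fs / n
  g <- exp(-(f - fc)^2 / (4 * sfc^2))
  X <- stats::fft(osc)
  W <- numeric(n)
  W[2:(half + 1)] <- g
  W[n:(n - half + 2)] <- g[seq_len(half - 1)]
  Re(stats::fft(X * W, inverse = TRUE)) / n
}

# Constant-envelope narrowband stochastic carrier: white noise shaped
# either by the standard Hamming FIR band-pass or by a Gaussian spectral
# window centered on the band (the band covering +/- 2 SD), then reduced to
# its instantaneous phase, cos(phi(t)). The Gaussian shape produces
# spectral humps inside the model family assumed by the
# aperiodic-plus-peaks parameterization. For the Gaussian shape the
# analytic signal is synthesized directly from a one-sided spectrum.
synth_carrier_norm <- function(spec, n, shape) {
  if (shape == "fir") {
    kern <- design_fir_bandpass(spec$band[1], spec$band[2],
                                spec$sampling_rate, transition_hz = 1)
    carrier <- fir_apply_zerophase(stats::rnorm(n), kern)
    return(carrier / pmax(Mod(analytic_signal(carrier)), 1e-12))
  }
  fs <- spec$sampling_rate
  fc <- mean(spec$band)
  sf <- diff(spec$band) / 4
  half <- floor(n / 2)
  f <- (1:half) * fs / n
  amp <- exp(-(f - fc)^2 / (4 * sf^2))  # amplitude = sqrt of Gaussian power
  X <- complex(length.out = n)
  X[2:(half + 1)] <- amp *
    complex(real = stats::rnorm(half), imaginary = stats::rnorm(half))
  a <- stats::fft(X, inverse = TRUE)    # analytic (one-sided) signal
  Re(a) / pmax(Mod(a), 1e-12)
}

#' Generate a signal with controlled amplitude-fluctuation coupling
#'
#' The oscillation envelope is built as `exp(mu) * (1 + sigma(t) * q)`,
#' where `mu` is a slow (window-scale-smoothed) fGn level process with the
#' requested Hurst exponent, `q` is a bounded zero-mean fluctuation process
#' band-limited between the filter timescale and the analysis window, and
#' the local volatility `sigma(t)` is a linear function of the standardized
#' level plus independent window-scale noise. The fE/I statistic's wDNF
#' measures exactly this local normalized fluctuation while wAmp follows
#' the level, so the Pearson correlation between window amplitude and
#' normalized detrended fluctuation approximates `spec$coupling_rho`.
#' Positive coupling yields fE/I < 1 (inhibition-dominated direction),
#' negative coupling fE/I > 1, zero coupling fE/I close to 1.
#'
#' @param spec a [signal_spec()]; `spec$coupling_rho` sets the target.
#' @param window_s analysis window length (s) at which the coupling is
#'   imposed; matches the fE/I estimator's resolution.
#' @param vol_base baseline local volatility of the envelope.
#' @param vol_gain relative swing of the volatility process.
#' @return Numeric vector of length `duration * sampling_rate` (microvolts).
#' @export
generate_coupled_signal <- function(spec, window_s = 5, vol_base = 0.3,
                                    vol_gain = 0.8,
                                    shape = c("fir", "gaussian"),
                                    confine = FALSE) {
  shape <- match.arg(shape)
  stopifnot(inherits(spec, "signal_spec"))
  if (is.null(spec$band)) stop("coupled generation requires an oscillation band")
  rho <- spec$coupling_rho
  fs <- spec$sampling_rate
  n <- round(spec$duration * fs)
  if (n < 2 * window_s * fs) stop("signal too short to impose window-scale coupling")
  set.seed(spec$seed)
  bg <- synth_background(n, fs, spec$aperiodic_offset, spec$aperiodic_beta,
                         spec$peak_list)
  L <- round(window_s * fs)
  zH <- generate_fgn(spec$hurst, n)
  mu <- smooth_ma(zH, L)
  mu <- spec$env_log_sd * mu / stats::sd(mu)  # full-strength level process
  muz <- as.numeric(scale(mu))
  knots <- unique(c(seq(1, n, by = L), n))
  nu <- stats::spline(knots, stats::rnorm(length(knots)), xout = seq_len(n))$y
  nu <- as.numeric(scale(nu))
  sigma <- pmin(0.6, pmax(0.02, vol_base * (1 + vol_gain *
    (rho * muz + sqrt(max(0, 1 - rho^2)) * nu))))
  # the fluctuation process q is band-limited between the filter's
  # smoothing timescale and the analysis window, bounded smoothly (so the
  # envelope never needs a hard positivity clamp, which would couple the
  # window mean to the volatility), and enters linearly so the window mean
  # (wAmp, following exp(mu)) stays independent of the local volatility
  # sigma that drives wDNF
  q <- generate_fgn(0.7, n)
  q <- smooth_ma(q, max(2L, round(0.5 * fs)))  # drop sub-filter timescales
  q <- q - smooth_ma(q, L)                     # drop super-window timescales
  q <- 1.5 * tanh(q / (1.5 * stats::sd(q)))
  env <- exp(mu) * (1 + sigma * q)
  carrier <- synth_carrier_norm(spec, n, shape)
  osc <- carrier * env
  if (confine) osc <- confine_to_band(osc, spec)
  bg + spec$osc_amplitude * osc / sqrt(mean(osc^2))
}

# Centered moving average (cumulative-sum implementation, O(n)) with edge
# padding.
smooth_ma <- function(x, k) {
  k <- as.integer(k)
  if (k <= 1) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- k %/% 2
  lo <- pmax(0L, seq_len(n) - 1L - half)
  hi <- pmin(n, seq_len(n) + (k - 1L - half))
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Inject stereotyped artifacts into a recording
#'
#' Adds (i) blink events: biphasic low-frequency waveforms projected with
#' frontally dominant weights, (ii) high-amplitude transient bursts
#' exceeding +/-150 uV on single channels, and (iii) optionally one flat
#' (zero-variance) channel. All events are returned in an event log with
#' sample indices.
#'
#' @param recording an `eeg_recording` with at least two frontal channels
#'   (Fp1/Fp2) when blinks are requested.
#' @param artifact_rates named list: `blinks_per_min`, `transients_per_min`,
#'   `flat_prob`.
#' @param seed integer seed.
#' @return List with elements `recording` (contaminated copy) and `events`
#'   (data frame: type, channel, sample).
#' @export
inject_artifacts <- function(recording,
                             artifact_rates = list(blinks_per_min = 2,
                                                   transients_per_min = 1,
                                                   flat_prob = 0),
                             seed = 1) {
  stopifnot(inherits(recording, "eeg_recording"))
  set.seed(as.integer(seed))
  x <- recording$signal
  fs <- recording$sampling_rate
  n <- ncol(x)
  dur_min <- n / fs / 60
  labs <- recording$channel_labels
  events <- list()

  br <- artifact_rates$blinks_per_min %||% 0
  if (br > 0) {
    if (!all(c("Fp1", "Fp2") %in% labs)) {
      stop("blink injection requires frontal channels Fp1 and Fp2")
    }
    nb <- stats::rpois(1, br * dur_min)
    wts <- blink_weights(labs)
    blen <- round(0.4 * fs)
    tt <- seq_len(blen) / fs
    shape <- exp(-(tt - 0.12)^2 / (2 * 0.05^2)) -
      0.4 * exp(-(tt - 0.26)^2 / (2 * 0.07^2))
    if (nb > 0) {
      starts <- sort(sample.int(max(1L, n - blen), nb))
      for (s in starts) {
        amp <- stats::runif(1, 90, 160)
        idx <- s:(s + blen - 1)
        x[, idx] <- x[, idx] + outer(wts, amp * shape)
        events[[length(events) + 1]] <-
          data.frame(type = "blink", channel = "Fp1/Fp2", sample = s)
      }
    }
  }

  tr <- artifact_rates$transients_per_min %||% 0
  if (tr > 0) {
    nt <- stats::rpois(1, tr * dur_min)
    tlen <- max(3L, round(0.05 * fs))
    burst <- sin(pi * seq_len(tlen) / (tlen + 1))
    if (nt > 0) {
      for (k in seq_len(nt)) {
        ch <- sample.int(nrow(x), 1)
        s <- sample.int(n - tlen, 1)
        amp <- sample(c(-1, 1), 1) * stats::runif(1, 170, 400)
        x[ch, s:(s + tlen - 1)] <- x[ch, s:(s + tlen - 1)] + amp * burst
        events[[length(events) + 1]] <-
          data.frame(type = "transient", channel = labs[ch], sample = s)
      }
    }
  }

  fp <- artifact_rates$flat_prob %||% 0
  if (fp > 0 && stats::runif(1) < fp) {
    ch <- sample.int(nrow(x), 1)
    x[ch, ] <- 0
    events[[length(events) + 1]] <-
      data.frame(type = "flat", channel = labs[ch], sample = 1L)
  }

  out <- recording
  out$signal <- x
  rownames(out$signal) <- labs
  list(recording = out,
       events = if (length(events)) do.call(rbind, events)
                else data.frame(type = character(), channel = character(),
                                sample = integer()))
}

blink_weights <- function(labels) {
  w <- rep(0.05, length(labels))
  names(w) <- labels
  for (nm in c("Fp1", "Fp2")) if (nm %in% labels) w[nm] <- 1
  for (nm in c("F7", "F8")) if (nm %in% labels) w[nm] <- 0.55
  for (nm in c("F3", "F4")) if (nm %in% labels) w[nm] <- 0.45
  if ("Fz" %in% labels) w["Fz"] <- 0.4
  for (nm in c("C3", "C4", "Cz")) if (nm %in% labels) w[nm] <- 0.15
  unname(w)
}

#' Specification of a synthetic two-group cohort
#'
#' @param n_control,n_patient group sizes (> 0).
#' @param age_range_control,age_range_patient age ranges in years.
#' @param effect_deltas named list of patient-group offsets:
#'   `delta_power_mult` (multiplier on delta-band oscillation power),
#'   `dfa_offset` (added to the 11-24 Hz envelope Hurst exponent),
#'   `coupling_offset` (added to the 12-24 Hz coupling rho; positive lowers
#'   fE/I), `beta_offset` (added to the aperiodic exponent).
#' @param artifact_rates named list passed to [inject_artifacts()]; all-zero
#'   rates (the default) yield artifact-free recordings.
#' @param montage ordered channel labels; must contain the 19 10-20 labels.
#' @param duration,sampling_rate per-recording signal length (s) and rate (Hz).
#' @param seed global integer seed; per-recording seeds are derived from it
#'   by a counter.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 50, n_patient = 14,
                        age_range_control = c(1, 17),
                        age_range_patient = c(1, 17),
                        effect_deltas = list(delta_power_mult = 2.2,
                                             dfa_offset = 0.12,
                                             coupling_offset = 0.55,
                                             beta_offset = 0.55),
                        artifact_rates = list(blinks_per_min = 0,
                                              transients_per_min = 0,
                                              flat_prob = 0),
                        montage = channels_1020(),
                        duration = 120, sampling_rate = 200, seed = 1) {
  if (n_control <= 0 || n_patient <= 0) stop("group sizes must be positive")
  if (!all(channels_1020() %in% normalize_labels(montage))) {
    stop("montage must contain all 19 10-20 labels")
  }
  defaults <- list(delta_power_mult = 2.2, dfa_offset = 0.12,
                   coupling_offset = 0.55, beta_offset = 0.55)
  defaults[names(effect_deltas)] <- effect_deltas
  structure(list(n_control = n_control, n_patient = n_patient,
                 age_range_control = age_range_control,
                 age_range_patient = age_range_patient,
                 effect_deltas = defaults, artifact_rates = artifact_rates,
                 montage = montage, duration = duration,
                 sampling_rate = sampling_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort of multichannel recordings
#'
#' Each recording carries, per channel, a 1/f^beta background, a delta-band
#' (2-4 Hz) oscillation whose power decreases with age in controls, an
#' alpha-band (8-13 Hz) oscillation, and an 11-24 Hz oscillation with a
#' tunable envelope Hurst exponent and amplitude-fluctuation coupling.
#' Patients receive the configured effect offsets scaled by a per-subject
#' severity factor; synthetic clinical scores (1-5) are generated to
#' correlate with that severity. Every injected property is logged in the
#' returned ground-truth table.
#'
#' @param spec a [cohort_spec()].
#' @return List with `recordings` (list of `eeg_recording`), `ground_truth`
#'   (one row per recording: injected Hurst, coupling, beta, delta
#'   multiplier, group, age, severity, clinical scores) and `artifact_log`
#'   (per-recording event data frames).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  ntot <- spec$n_control + spec$n_patient
  seeds <- derive_seeds(spec$seed, 3L * ntot)
  groups <- c(rep("control", spec$n_control), rep("patient", spec$n_patient))
  eff <- spec$effect_deltas
  recs <- vector("list", ntot)
  logs <- vector("list", ntot)
  gt <- vector("list", ntot)
  for (i in seq_len(ntot)) {
    set.seed(seeds[i])
    grp <- groups[i]
    rng <- if (grp == "control") spec$age_range_control else spec$age_range_patient
    age <- stats::runif(1, rng[1], rng[2])
    sev <- if (grp == "patient") stats::runif(1, 0.6, 1.4) else 0
    beta_i <- 1.3 + stats::rnorm(1, 0, 0.12) + sev * eff$beta_offset
    dmult_i <- (if (grp == "patient") eff$delta_power_mult^sev else 1) *
      exp(stats::rnorm(1, 0, 0.15))
    hurst_i <- min(0.95, 0.60 + stats::rnorm(1, 0, 0.02) + sev * eff$dfa_offset)
    rho_i <- max(-0.9, min(0.9, stats::rnorm(1, 0, 0.05) +
                                 sev * eff$coupling_offset))
    # delta power declines with age along the typical developmental
    # trajectory (log10 power slope -0.04 / year); patients deviate from it
    # (flat trajectory) only when a delta-power effect is injected, so a
    # cohort with all-zero effects is a true null
    flat <- grp == "patient" && eff$delta_power_mult != 1
    age_mult <- if (flat) 1 else 10^(-0.02 * age)
    sig <- synth_recording_channels(spec, seed = seeds[ntot + i],
                                    beta = beta_i,
                                    delta_amp = 4.5 * sqrt(dmult_i) * age_mult,
                                    hurst_high = hurst_i, rho_high = rho_i)
    rec <- eeg_recording(sig, spec$sampling_rate, spec$montage,
                         subject = list(id = sprintf("S%03d", i), group = grp,
                                        age = age, site = "synthetic"),
                         reference = "common")
    inj <- inject_artifacts(rec, spec$artifact_rates,
                            seed = seeds[2L * ntot + i])
    scores <- synth_clinical_scores(grp, sev)
    rec <- inj$recording
    rec$subject$clinical_scores <- scores
    recs[[i]] <- rec
    logs[[i]] <- inj$events
    gt[[i]] <- data.frame(id = rec$subject$id, group = grp, age = age,
                          severity = sev, hurst_high = hurst_i,
                          coupling_rho = rho_i, beta = beta_i,
                          delta_mult = dmult_i,
                          GMFCS = scores$GMFCS %||% NA_real_,
                          MACS = scores$MACS %||% NA_real_,
                          CFCS = scores$CFCS %||% NA_real_)
  }
  list(recordings = recs, ground_truth = do.call(rbind, gt),
       artifact_log = logs)
}

# One subject's channels x samples matrix. Channel-level amplitude maps give
# posterior-dominant alpha and frontal-dominant delta; small per-channel
# jitter decorrelates channels.
synth_recording_channels <- function(spec, seed, beta, delta_amp,
                                     hurst_high, rho_high) {
  labs <- spec$montage
  nch <- length(labs)
  chseeds <- derive_seeds(seed, nch)
  amap <- alpha_weights(labs)
  dmap <- delta_weights(labs)
  sig <- matrix(0, nch, round(spec$duration * spec$sampling_rate))
  for (c in seq_len(nch)) {
    base <- signal_spec(spec$duration, spec$sampling_rate, band = NULL,
                        aperiodic_beta = beta, aperiodic_offset = 1.3,
                        seed = chseeds[c])
    x <- generate_band_signal(base)
    set.seed(chseeds[c] + 1L)
    d <- signal_spec(spec$duration, spec$sampling_rate, band = c(2, 4),
                     hurst = 0.58, osc_amplitude = delta_amp * dmap[c],
                     aperiodic_beta = beta, seed = chseeds[c] + 1L)
    x <- x + synth_oscillation(d, ncol(sig), shape = "gaussian", confine = TRUE)
    a <- signal_spec(spec$duration, spec$sampling_rate, band = c(8, 13),
                     hurst = 0.62, osc_amplitude = 3.5 * amap[c],
                     aperiodic_beta = beta, seed = chseeds[c] + 2L)
    set.seed(chseeds[c] + 2L)
    x <- x + synth_oscillation(a, ncol(sig), shape = "gaussian", confine = TRUE)
    # high-frequency content: a low-beta oscillation (11-18 Hz) carrying
    # the envelope Hurst exponent, and a volatility-coupled beta
    # oscillation (18-24 Hz) carrying the amplitude-fluctuation coupling;
    # Gaussian spectral shapes keep the humps inside the family the
    # spectral parameterization can absorb
    hb <- signal_spec(spec$duration, spec$sampling_rate, band = c(11, 18),
                      hurst = hurst_high, osc_amplitude = 7,
                      env_log_sd = 0.9, aperiodic_beta = 0.8,
                      aperiodic_offset = -1.2, seed = chseeds[c] + 3L)
    set.seed(chseeds[c] + 3L)
    x <- x + synth_oscillation(hb, ncol(sig), shape = "gaussian", confine = TRUE)
    cp <- signal_spec(spec$duration, spec$sampling_rate, band = c(18, 24),
                      hurst = 0.6, coupling_rho = rho_high,
                      osc_amplitude = 6, env_log_sd = 0.4,
                      aperiodic_beta = 0.8, aperiodic_offset = -1.2,
                      seed = chseeds[c] + 4L)
    x <- x + generate_coupled_signal(cp, shape = "gaussian", confine = TRUE)
    sig[c, ] <- x
  }
  rownames(sig) <- labs
  sig
}

alpha_weights <- function(labels) {
  w <- rep(0.8, length(labels))
  names(w) <- labels
  for (nm in c("O1", "O2", "P3", "P4", "Pz", "T5", "T6")) {
    if (nm %in% labels) w[nm] <- 1.3
  }
  unname(w)
}

delta_weights <- function(labels) {
  w <- rep(1, length(labels))
  names(w) <- labels
  for (nm in c("Fp1", "Fp2", "F3", "F4", "Fz")) if (nm %in% labels) w[nm] <- 1.2
  unname(w)
}

# Clinical scores (1-5 Likert) increasing with injected severity; MACS is
# occasionally missing, mirroring partially available clinical scales.
synth_clinical_scores <- function(group, severity) {
  if (group != "patient") return(NULL)
  one <- function(noise_sd) {
    raw <- 1 + 4 * stats::pnorm((severity - 1) / 0.35 + stats::rnorm(1, 0, noise_sd))
    max(1, min(5, round(raw)))
  }
  list(GMFCS = one(0.6), MACS = if (stats::runif(1) < 0.15) NA else one(0.6),
       CFCS = one(0.6))
}

#' Heterogeneous multichannel recording for rate-robustness checks
#'
#' A 19-channel recording whose channels differ systematically in aperiodic
#' exponent, alpha-envelope Hurst exponent, and beta-band
#' amplitude-fluctuation coupling, so that per-electrode, per-bin biomarker
#' values span a wide range. Used to quantify the agreement of measures
#' computed at the original and a downsampled rate.
#'
#' @param seed integer seed.
#' @param duration duration in seconds.
#' @param sampling_rate sampling rate in Hz.
#' @return An `eeg_recording` on the 19-channel 10-20 montage.
#' @export
resampling_demo_recording <- function(seed = 1, duration = 300,
                                      sampling_rate = 1000) {
  labs <- channels_1020()
  fs <- sampling_rate
  n <- round(duration * fs)
  chseeds <- derive_seeds(seed, 19L)
  sig <- matrix(0, 19, n)
  for (c in 1:19) {
    set.seed(chseeds[c])
    base <- signal_spec(duration, fs, band = NULL,
                        aperiodic_beta = 0.9 + 0.05 * c,
                        aperiodic_offset = 1.1, seed = chseeds[c])
    x <- generate_band_signal(base)
    d <- signal_spec(duration, fs, band = c(2, 4),
                     hurst = 0.5 + 0.018 * c, osc_amplitude = 4,
                     seed = chseeds[c] + 1L)
    set.seed(chseeds[c] + 1L)
    x <- x + synth_oscillation(d, n, shape = "gaussian", confine = TRUE)
    a <- signal_spec(duration, fs, band = c(8, 13),
                     hurst = 0.52 + 0.02 * c, osc_amplitude = 5,
                     env_log_sd = 1, seed = chseeds[c] + 2L)
    set.seed(chseeds[c] + 2L)
    x <- x + synth_oscillation(a, n, shape = "gaussian", confine = TRUE)
    cp <- signal_spec(duration, fs, band = c(14, 24), hurst = 0.6,
                      coupling_rho = -0.6 + 0.07 * c, osc_amplitude = 5,
                      env_log_sd = 0.4, aperiodic_beta = 0.8,
                      aperiodic_offset = -1.2, seed = chseeds[c] + 3L)
    x <- x + generate_coupled_signal(cp, shape = "gaussian", confine = TRUE)
    sig[c, ] <- x
  }
  eeg_recording(sig, fs, labs,
                subject = list(id = sprintf("RDEMO%d", seed),
                               group = "control", age = 10))
}

#' Analytic synthetic power spectrum
#'
#' Builds a power spectrum directly from an aperiodic component plus
#' Gaussian peaks (in log10 space) with multiplicative noise -- the
#' generative family assumed by the spectral parameterization module; used
#' to validate exponent recovery.
#'
#' @param frequencies frequency grid (Hz, > 0).
#' @param offset,exponent aperiodic offset (log10 power) and exponent.
#' @param peak_list list of `c(center_hz, height_log10, width_hz)` triples.
#' @param noise_sd SD of multiplicative log-normal noise (0.05 = 5%).
#' @param seed integer seed.
#' @return A `psd_spectrum` object with one channel.
#' @export
synthetic_spectrum <- function(frequencies, offset, exponent,
                               peak_list = list(), noise_sd = 0,
                               seed = 1) {
  stopifnot(all(frequencies > 0))
  set.seed(as.integer(seed))
  logS <- offset - exponent * log10(frequencies)
  for (p in peak_list) {
    logS <- logS + p[2] * exp(-(frequencies - p[1])^2 / (2 * p[3]^2))
  }
  pw <- 10^logS
  if (noise_sd > 0) pw <- pw * exp(stats::rnorm(length(pw), 0, noise_sd))
  new_psd_spectrum(matrix(pw, nrow = 1, dimnames = list("synthetic", NULL)),
                   frequencies,
                   params = list(kind = "synthetic", offset = offset,
                                 exponent = exponent))
}
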