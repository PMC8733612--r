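# Sensor-level preprocessing chain: band-pass filtering, automated
# bad-channel detection, spherical-spline interpolation, average
# re-referencing, 10-20 channel selection, 1-s epoching with amplitude
# rejection, ICA-based ocular artifact removal, cleaning report.

#' Zero-phase FIR band-pass filter for recordings
#'
#' Hamming-window FIR design with the requested transition bandwidth,
#' applied without phase distortion (group delay compensated); output length
#' equals input length.
#'
#' @param x an `eeg_recording`, or numeric vector/matrix (channels x
#'   samples).
#' @param low_hz,high_hz passband edges (Hz).
#' @param sampling_rate required for bare vectors/matrices.
#' @param transition_hz transition bandwidth (Hz).
#' @return Same type as the input, filtered.
#' @export
bandpass_fir <- function(x, low_hz = 1, high_hz = 45, sampling_rate = NULL,
                         transition_hz = 1) {
  if (inherits(x, "eeg_recording")) {
    x$signal <- bandpass_fir(x$signal, low_hz, high_hz, x$sampling_rate,
                             transition_hz)
    return(x)
  }
  if (is.null(sampling_rate)) stop("sampling_rate required")
  kern <- design_fir_bandpass(low_hz, high_hz, sampling_rate, transition_hz)
  if (is.matrix(x)) {
    t(apply(x, 1, fir_apply_zerophase, kernel = kern))
  } else {
    fir_apply_zerophase(x, kern)
  }
}

#' Automated bad-channel detection
#'
#' A channel is flagged when the z-score, computed across channels, of any
#' of three statistics exceeds 3 in absolute value: (i) the kurtosis of its
#' samples, (ii) its mean negative log-probability under a Gaussian
#' kernel-density estimate of its own amplitude distribution (the "joint
#' probability" statistic), or (iii) its mean log band power over
#' 1-45 Hz. Zero-variance (flat) channels are always flagged.
#'
#' @param recording an `eeg_recording` with at least 8 channels.
#' @param z_threshold flag threshold on the absolute z-score.
#' @return Logical vector, one flag per channel, with attribute `"scores"`
#'   (the per-channel z-score matrix).
#' @export
detect_bad_channels <- function(recording, z_threshold = 3) {
  stopifnot(inherits(recording, "eeg_recording"))
  x <- recording$signal
  if (nrow(x) < 8) stop("need at least 8 channels for stable z-scores")
  flat <- apply(x, 1, stats::var) == 0
  kurt <- apply(x, 1, function(v) {
    if (stats::var(v) == 0) NA_real_ else e1071::kurtosis(v, type = 2)
  })
  nlp <- apply(x, 1, function(v) {
    if (stats::var(v) == 0) return(NA_real_)
    d <- stats::density(v, bw = "nrd0", n = 512)
    f <- stats::approx(d$x, d$y, xout = v, rule = 2)$y
    -mean(log(pmax(f, 1e-300)))
  })
  psd <- welch_psd(x, recording$sampling_rate)
  sel <- psd$frequencies >= 1 & psd$frequencies <= 45
  lbp <- log10(rowMeans(psd$power[, sel, drop = FALSE]))
  lbp[flat] <- NA_real_
  scores <- cbind(kurtosis = zscore(kurt), jointprob = zscore(nlp),
                  logpower = zscore(lbp))
  rownames(scores) <- recording$channel_labels
  flags <- flat | apply(abs(scores) > z_threshold, 1, any, na.rm = TRUE)
  names(flags) <- recording$channel_labels
  attr(flags, "scores") <- scores
  flags
}

zscore <- function(v) (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)

#' Spherical-spline interpolation of flagged channels
#'
#' Replaces flagged channels with spherical-spline estimates (Perrin-style,
#' spline order m = 4, Legendre series truncated at 50 terms, small ridge
#' term on the diagonal) computed from all good channels using idealized
#' unit-sphere electrode positions. Good channels are returned unchanged.
#'
#' @param recording an `eeg_recording` whose labels have known idealized
#'   positions.
#' @param flags logical vector, one per channel (from
#'   [detect_bad_channels()]).
#' @param positions optional n x 3 matrix of unit-sphere coordinates.
#' @param m spline order.
#' @param n_legendre number of Legendre terms.
#' @param ridge ridge regularization added to the spline system diagonal.
#' @return The recording with flagged channels interpolated.
#' @export
spherical_spline_interpolate <- function(recording, flags, positions = NULL,
                                         m = 4, n_legendre = 50,
                                         ridge = 1e-5) {
  stopifnot(inherits(recording, "eeg_recording"))
  flags <- as.logical(flags)
  if (!any(flags)) return(recording)
  if (all(flags)) stop("all channels are flagged; nothing to interpolate from")
  if (sum(!flags) < 4) stop("need at least 4 good channels")
  if (is.null(positions)) positions <- electrode_positions(recording$channel_labels)
  positions <- positions / sqrt(rowSums(positions^2))
  good <- which(!flags)
  bad <- which(flags)
  cosgg <- tcrossprod(positions[good, , drop = FALSE])
  cosbg <- positions[bad, , drop = FALSE] %*% t(positions[good, , drop = FALSE])
  G <- spline_g(cosgg, m, n_legendre)
  Gb <- spline_g(cosbg, m, n_legendre)
  ng <- length(good)
  A <- rbind(cbind(G + diag(ridge, ng), rep(1, ng)), c(rep(1, ng), 0))
  rhs <- rbind(recording$signal[good, , drop = FALSE],
               rep(0, ncol(recording$signal)))
  sol <- solve(A, rhs)
  est <- Gb %*% sol[seq_len(ng), , drop = FALSE] +
    matrix(sol[ng + 1, ], length(bad), ncol(recording$signal), byrow = TRUE)
  recording$signal[bad, ] <- est
  recording
}

# Perrin g function: sum over n of (2n+1) / (n (n+1))^m P_n(cos) / (4 pi).
spline_g <- function(cosang, m, n_legendre) {
  cosang <- pmin(pmax(cosang, -1), 1)  # first arg keeps the matrix dims
  x <- as.vector(cosang)
  # Legendre recurrence evaluated for all needed degrees at once
  pkm1 <- rep(1, length(x))   # P_0
  pk <- x                     # P_1
  out <- (2 * 1 + 1) / (1 * 2)^m * pk
  for (nn in 2:n_legendre) {
    pkp1 <- ((2 * nn - 1) * x * pk - (nn - 1) * pkm1) / nn
    out <- out + (2 * nn + 1) / (nn * (nn + 1))^m * pkp1
    pkm1 <- pk
    pk <- pkp1
  }
  matrix(out / (4 * pi), nrow(cosang), ncol(cosang))
}

#' Average re-reference
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the per-sample channel mean is zero. Idempotent.
#'
#' @param recording an `eeg_recording` with >= 2 channels.
#' @return The re-referenced recording (`reference = "average"`).
#' @export
average_rereference <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"), nrow(recording$signal) >= 2)
  recording$signal <- sweep(recording$signal, 2, colMeans(recording$signal))
  recording$reference <- "average"
  recording
}

#' Select the 19 standard 10-20 channels
#'
#' Reduces a recording to the 19-channel 10-20 set in the canonical order
#' (see [channels_1020()]); modern aliases (T7/T8/P7/P8) are resolved.
#'
#' @param recording an `eeg_recording` containing all 19 channels (directly
#'   or via alias).
#' @return A 19-channel recording in canonical order.
#' @export
select_1020_channels <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  norm <- normalize_labels(recording$channel_labels)
  want <- channels_1020()
  missing <- setdiff(want, norm)
  if (length(missing) > 0) {
    stop("montage is missing channel(s): ", paste(missing, collapse = ", "))
  }
  idx <- match(want, norm)
  recording$signal <- recording$signal[idx, , drop = FALSE]
  recording$channel_labels <- want
  rownames(recording$signal) <- want
  recording
}

#' Segment into 1-s epochs with amplitude rejection
#'
#' Splits the recording into non-overlapping 1-s epochs (a trailing partial
#' second is discarded) and marks an epoch as rejected when any sample on
#' any channel falls outside `[-amplitude_limit, amplitude_limit]` microvolts.
#'
#' @param recording an `eeg_recording` at least 1 s long.
#' @param amplitude_limit rejection threshold in microvolts (default 150; a
#'   per-recording override of 500 is used for recordings with a larger
#'   artifact-free amplitude range).
#' @param external_keep optional logical vector overriding the keep mask
#'   (e.g. an expert review mask); combined by logical AND.
#' @return An `eeg_epochs` object: `epochs` (n_epochs x channels x samples),
#'   `keep_mask`, `amplitude_limit`, `sampling_rate`, `channel_labels`.
#' @export
segment_and_reject <- function(recording, amplitude_limit = 150,
                               external_keep = NULL) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$sampling_rate
  spe <- round(fs)
  nep <- floor(ncol(recording$signal) / spe)
  if (nep < 1) stop("recording shorter than one epoch")
  nch <- nrow(recording$signal)
  ep <- array(NA_real_, c(nep, nch, spe))
  keep <- logical(nep)
  for (i in seq_len(nep)) {
    seg <- recording$signal[, ((i - 1) * spe + 1):(i * spe), drop = FALSE]
    ep[i, , ] <- seg
    keep[i] <- all(abs(seg) <= amplitude_limit)
  }
  if (!is.null(external_keep)) {
    stopifnot(length(external_keep) == nep)
    keep <- keep & external_keep
  }
  structure(list(epochs = ep, keep_mask = keep,
                 amplitude_limit = amplitude_limit, sampling_rate = fs,
                 channel_labels = recording$channel_labels,
                 subject = recording$subject),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d x 1-s epochs (%d kept, limit %g uV), %d channels @ %g Hz\n",
              length(x$keep_mask), sum(x$keep_mask), x$amplitude_limit,
              dim(x$epochs)[2], x$sampling_rate))
  invisible(x)
}

# Contiguous runs of kept epochs, each as a channels x samples matrix.
epoch_runs <- function(epoch_set) {
  keep <- epoch_set$keep_mask
  if (!any(keep)) stop("no epochs kept")
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- list()
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    idx <- starts[k]:ends[k]
    run <- do.call(cbind, lapply(idx, function(i)
      matrix(epoch_set$epochs[i, , ], dim(epoch_set$epochs)[2])))
    rownames(run) <- epoch_set$channel_labels
    out[[length(out) + 1]] <- run
  }
  out
}

# All kept epochs concatenated into one channels x samples matrix.
epochs_to_matrix <- function(epoch_set) {
  do.call(cbind, epoch_runs(epoch_set))
}

#' Total kept signal length in seconds
#' @param epoch_set an `eeg_epochs`.
#' @return Seconds of kept signal.
#' @export
clean_length <- function(epoch_set) {
  sum(epoch_set$keep_mask) * dim(epoch_set$epochs)[3] / epoch_set$sampling_rate
}

#' Remove ocular ICA components
#'
#' Concatenated kept epochs are reduced to their numerical rank by PCA,
#' decomposed with FastICA (symmetric orthogonalization, logcosh contrast,
#' fixed seed), and each component is scored by a documented heuristic: a
#' component is called ocular when more than `lowfreq_frac` of its variance
#' lies below `lowfreq_hz` Hz and the mean absolute topography weight over
#' the frontal channels (Fp1, Fp2, F7, F8) exceeds `frontal_ratio` times the
#' mean over all channels. Flagged components are zeroed and the epochs
#' reconstructed.
#'
#' @param epoch_set an `eeg_epochs` with >= 60 s of kept epochs.
#' @param seed integer seed for the ICA initialization.
#' @param lowfreq_hz,lowfreq_frac,frontal_ratio heuristic thresholds.
#' @param min_seconds minimum kept signal length required for a stable
#'   decomposition.
#' @return List: `epochs` (cleaned `eeg_epochs`), `report` (flagged
#'   component indices, per-component scores, topographies, rank).
#' @export
remove_ocular_components <- function(epoch_set, seed = 1, lowfreq_hz = 5,
                                     lowfreq_frac = 0.6, frontal_ratio = 2,
                                     min_seconds = 60) {
  stopifnot(inherits(epoch_set, "eeg_epochs"))
  if (clean_length(epoch_set) < min_seconds) {
    stop("need at least ", min_seconds, " s of kept epochs for ICA")
  }
  x <- epochs_to_matrix(epoch_set)
  mu <- rowMeans(x)
  xc <- x - mu
  cv <- tcrossprod(xc) / ncol(xc)
  eg <- eigen(cv, symmetric = TRUE)
  rank <- sum(eg$values > max(eg$values) * 1e-7)
  if (rank < 2) stop("channel data rank below 2; cannot decompose")
  U <- eg$vectors[, seq_len(rank), drop = FALSE]
  D <- sqrt(eg$values[seq_len(rank)])
  Z <- crossprod(U, xc) / D          # whitened (rank x samples)
  W <- fastica_symm(Z, seed = seed)  # rank x rank orthonormal
  S <- W %*% Z                       # sources
  A <- U %*% (D * t(W))              # channel-space mixing (ch x rank)
  fs <- epoch_set$sampling_rate
  frontal <- which(epoch_set$channel_labels %in% c("Fp1", "Fp2", "F7", "F8"))
  scores <- t(vapply(seq_len(rank), function(j) {
    psd <- welch_psd(S[j, ], fs)
    keepf <- psd$frequencies > 0
    lf <- sum(psd$power[1, psd$frequencies <= lowfreq_hz & keepf]) /
      sum(psd$power[1, keepf])
    fr <- if (length(frontal) > 0) {
      mean(abs(A[frontal, j])) / mean(abs(A[, j]))
    } else 0
    c(lowfreq_frac = lf, frontal_ratio = fr)
  }, c(lowfreq_frac = 0, frontal_ratio = 0)))
  flagged <- which(scores[, "lowfreq_frac"] > lowfreq_frac &
                   scores[, "frontal_ratio"] > frontal_ratio)
  if (length(flagged) > 0) {
    Sc <- S
    Sc[flagged, ] <- 0
    xclean <- A %*% Sc + mu
    out <- epoch_set
    spe <- dim(epoch_set$epochs)[3]
    kept <- which(epoch_set$keep_mask)
    for (k in seq_along(kept)) {
      out$epochs[kept[k], , ] <- xclean[, ((k - 1) * spe + 1):(k * spe)]
    }
  } else {
    out <- epoch_set
  }
  list(epochs = out,
       report = list(flagged = flagged, scores = scores, topographies = A,
                     rank = rank, n_removed = length(flagged)))
}

# FastICA with symmetric orthogonalization and logcosh contrast on whitened
# data (components x samples). Deterministic under the given seed.
fastica_symm <- function(Z, seed = 1, max_iter = 200, tol = 1e-6) {
  r <- nrow(Z)
  n <- ncol(Z)
  set.seed(as.integer(seed))
  W <- matrix(stats::rnorm(r * r), r)
  W <- sym_orth(W)
  for (it in seq_len(max_iter)) {
    Y <- W %*% Z
    G <- tanh(Y)
    gprime <- rowMeans(1 - G^2)
    Wn <- G %*% t(Z) / n - gprime * W
    Wn <- sym_orth(Wn)
    delta <- max(abs(abs(rowSums(Wn * W)) - 1))
    W <- Wn
    if (delta < tol) break
  }
  W
}

sym_orth <- function(W) {
  s <- svd(W)
  s$u %*% t(s$v)
}

#' Compile the cleaning report
#'
#' Aggregates the preprocessing statistics for one recording: percentage of
#' bad channels (in the full montage and within the 19 selected channels),
#' percentage of rejected epochs, number of removed ICA components, and
#' clean signal length.
#'
#' @param flags_all logical flags over the original montage.
#' @param flags_1020 logical flags restricted to the 19 selected channels.
#' @param epoch_set the post-rejection `eeg_epochs`.
#' @param n_components_removed number of zeroed ICA components.
#' @return A `cleaning_report` (also a plain list, serializable to JSON).
#' @export
compile_cleaning_report <- function(flags_all, flags_1020, epoch_set,
                                    n_components_removed = 0) {
  rep <- list(
    pct_bad_channels_all = 100 * mean(flags_all),
    pct_bad_channels_1020 = 100 * mean(flags_1020),
    pct_bad_epochs = 100 * mean(!epoch_set$keep_mask),
    n_components_removed = n_components_removed,
    clean_signal_length = clean_length(epoch_set),
    interpolated = names(which(flags_all))
  )
  structure(rep, class = c("cleaning_report", "list"))
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf(paste0("<cleaning_report> bad channels %.1f%% (10-20: %.1f%%), ",
                     "bad epochs %.1f%%, %d IC removed, %.0f s clean\n"),
              x$pct_bad_channels_all, x$pct_bad_channels_1020,
              x$pct_bad_epochs, x$n_components_removed,
              x$clean_signal_length))
  invisible(x)
}

#' Run the full preprocessing chain on one recording
#'
#' Band-pass filter (1-45 Hz), bad-channel detection and spherical-spline
#' interpolation on the full montage, average re-reference, selection of the
#' 19 10-20 channels, 1-s epoching with amplitude rejection, and ICA-based
#' ocular component removal. Returns the cleaned epochs plus the cleaning
#' report.
#'
#' @param recording an `eeg_recording`.
#' @param amplitude_limit epoch rejection threshold (uV).
#' @param ica_seed seed for the ICA step.
#' @param run_ica set `FALSE` to skip ocular removal (e.g. very short
#'   recordings).
#' @param external_keep optional expert keep mask (see
#'   [segment_and_reject()]).
#' @return List: `epochs` (cleaned `eeg_epochs`), `report`
#'   (`cleaning_report`), `ica` (component report or `NULL`).
#' @export
preprocess_recording <- function(recording, amplitude_limit = 150,
                                 ica_seed = 1, run_ica = TRUE,
                                 external_keep = NULL) {
  rec <- bandpass_fir(recording, 1, 45)
  flags <- detect_bad_channels(rec)
  if (any(flags) && !all(flags)) {
    rec <- spherical_spline_interpolate(rec, flags)
  }
  rec <- average_rereference(rec)
  rec19 <- select_1020_channels(rec)
  norm <- normalize_labels(recording$channel_labels)
  flags_1020 <- flags[match(channels_1020(), norm)]
  eps <- segment_and_reject(rec19, amplitude_limit, external_keep)
  ica_rep <- NULL
  n_rm <- 0
  if (run_ica && clean_length(eps) >= 60) {
    res <- remove_ocular_components(eps, seed = ica_seed)
    eps <- res$epochs
    ica_rep <- res$report
    n_rm <- res$report$n_removed
  }
  report <- compile_cleaning_report(flags, flags_1020, eps, n_rm)
  list(epochs = eps, report = report, ica = ica_rep)
}
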