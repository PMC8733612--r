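# End-to-end orchestration: simulate -> preprocess -> measures ->
# aperiodic -> statistics, plus the resampling-robustness utility.

#' Default pipeline configuration
#'
#' All module parameters with their standard values: 1-45 Hz analysis band,
#' 150 uV epoch rejection (per-recording overrides possible), 0.125-Hz
#' power resolution, 1-Hz DFA/fE/I bins, DFA scale rules 2-20 s / 4-20 s,
#' fE/I validity switch, 1-30 Hz aperiodic fit, band definitions for the
#' four headline summaries, and Bonferroni families (353 power bins, 44
#' DFA/fE/I bins, 19 electrodes).
#'
#' @return Nested named list; serializable with [yaml::write_yaml()].
#' @export
default_config <- function() {
  list(
    version = "1",
    seed = 1,
    stages = list(simulate = TRUE, preprocess = TRUE, measures = TRUE,
                  aperiodic = TRUE, stats = TRUE),
    cohort = list(n_control = 50, n_patient = 14, duration = 120,
                  sampling_rate = 200),
    preprocess = list(band = c(1, 45), amplitude_limit = 150,
                      amplitude_overrides = list(), ica_seed = 1,
                      run_ica = TRUE, min_clean_s = 100),
    measures = list(dfa_bins = 1:44, fei_bins = 1:44,
                    fei_validity_threshold = 0.6, fei_apply_validity = TRUE,
                    power_band = c(1, 45)),
    aperiodic = list(fit_range = c(1, 30)),
    bands = list(delta = c(1.75, 4.625), dfa = c(11, 18), fei = c(12, 24)),
    stats = list(alpha = 0.05, m_power = 353, m_dfa = 44, m_fei = 44,
                 m_electrodes = 19)
  )
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it over [default_config()] (missing keys
#' keep their defaults).
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Whole-brain headline measures for a set of recordings
#'
#' Computes, per subject: mean log10 delta-band power (1.75-4.625 Hz),
#' whole-brain DFA in 11-18 Hz, whole-brain fE/I in 12-24 Hz, and the mean
#' aperiodic exponent (1-30 Hz fit), along with the per-electrode values
#' behind each summary. Whole-brain values are electrode means; power is
#' averaged in log10 units.
#'
#' @param inputs list of `eeg_recording` or `eeg_epochs` objects (cleaned).
#' @param config pipeline configuration (band definitions, validity rule).
#' @param min_length_s minimum clean length for DFA/fE/I.
#' @param progress print one line per subject.
#' @return List: `summaries` (data frame, one row per subject),
#'   `electrode` (list of subjects x electrodes matrices per measure).
#' @export
headline_measures <- function(inputs, config = default_config(),
                              min_length_s = 100, progress = FALSE) {
  bands <- config$bands
  dfa_bins <- seq(bands$dfa[1], bands$dfa[2] - 1)
  fei_bins <- seq(bands$fei[1], bands$fei[2] - 1)
  n <- length(inputs)
  rows <- vector("list", n)
  el <- list(delta_power = NULL, dfa = NULL, fei = NULL, exponent = NULL)
  all_bins <- sort(unique(c(dfa_bins, fei_bins)))
  for (i in seq_len(n)) {
    x <- inputs[[i]]
    psd <- welch_psd(x)
    dp <- log10(band_average_power(psd, bands$delta[1], bands$delta[2]))
    runs <- signal_runs(x)
    total_s <- sum(vapply(runs$runs, ncol, 1L)) / runs$fs
    if (total_s < min_length_s) {
      stop(sprintf("clean signal length %.1f s is below the %g s minimum",
                   total_s, min_length_s))
    }
    core <- measure_core(runs$runs, runs$fs, all_bins,
                         want = c("dfa", "fei"),
                         fei_validity_threshold = config$measures$fei_validity_threshold,
                         fei_apply_validity = config$measures$fei_apply_validity)
    dfa <- structure(list(measure = "dfa", bins = all_bins,
                          values = core$dfa, validity = core$validity$dfa),
                     class = "measure_spectrum")
    fei <- structure(list(measure = "fei", bins = all_bins,
                          values = core$fei, validity = core$validity$fei),
                     class = "measure_spectrum")
    ap <- fit_spectral_model(psd, fit_range = config$aperiodic$fit_range)
    if (inherits(ap, "aperiodic_fit")) ap <- list(ap)
    expo <- vapply(ap, function(f) f$exponent, 0)
    dfa_el <- band_summary(dfa, bands$dfa[1], bands$dfa[2])
    fei_el <- band_summary(fei, bands$fei[1], bands$fei[2])
    subj <- if (inherits(x, "eeg_recording") || inherits(x, "eeg_epochs")) {
      x$subject
    } else list()
    rows[[i]] <- data.frame(
      id = subj$id %||% paste0("S", i),
      group = subj$group %||% NA_character_,
      age = subj$age %||% NA_real_,
      delta_power = mean(dp), dfa = mean(dfa_el), fei = mean(fei_el),
      exponent = mean(expo))
    el$delta_power <- rbind(el$delta_power, dp)
    el$dfa <- rbind(el$dfa, dfa_el)
    el$fei <- rbind(el$fei, fei_el)
    el$exponent <- rbind(el$exponent, expo)
    if (progress) message(sprintf("  subject %d/%d done", i, n))
  }
  list(summaries = do.call(rbind, rows), electrode = el)
}

#' Run the full pipeline
#'
#' Orchestrates simulate -> preprocess -> measures -> aperiodic -> stats
#' under a single configuration, writing every intermediate table as CSV
#' plus a JSON manifest (software version, config hash, per-recording
#' cleaning statistics, quarantined recordings). Deterministic given the
#' configuration.
#'
#' @param config configuration list (see [default_config()]) or a YAML
#'   path.
#' @param out_dir output directory (created if missing).
#' @param recordings optional list of `eeg_recording`s; required when the
#'   simulate stage is disabled.
#' @return Invisibly, a list with the subject measures, statistics tables
#'   and cleaning reports.
#' @export
run_pipeline <- function(config = default_config(), out_dir, recordings = NULL) {
  if (is.character(config)) config <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ground_truth <- NULL
  if (isTRUE(config$stages$simulate)) {
    cs <- do.call(cohort_spec, c(config$cohort, list(seed = config$seed)))
    cohort <- generate_cohort(cs)
    recordings <- cohort$recordings
    ground_truth <- cohort$ground_truth
    utils::write.csv(ground_truth, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  if (is.null(recordings)) stop("no recordings: enable the simulate stage or supply recordings")

  inputs <- recordings
  cleaning <- NULL
  quarantine <- list()
  if (isTRUE(config$stages$preprocess)) {
    inputs <- list()
    reports <- list()
    for (i in seq_along(recordings)) {
      rec <- recordings[[i]]
      id <- rec$subject$id %||% paste0("S", i)
      lim <- config$preprocess$amplitude_overrides[[id]] %||%
        config$preprocess$amplitude_limit
      res <- tryCatch(
        preprocess_recording(rec, amplitude_limit = lim,
                             ica_seed = config$preprocess$ica_seed,
                             run_ica = config$preprocess$run_ica),
        error = function(e) e)
      if (inherits(res, "error")) {
        quarantine[[id]] <- conditionMessage(res)
        next
      }
      if (res$report$clean_signal_length < config$preprocess$min_clean_s) {
        quarantine[[id]] <- sprintf(
          "clean signal %.1f s below the %g s inclusion minimum",
          res$report$clean_signal_length, config$preprocess$min_clean_s)
        next
      }
      res$epochs$subject <- rec$subject
      inputs[[length(inputs) + 1]] <- res$epochs
      reports[[id]] <- res$report
    }
    cleaning <- do.call(rbind, lapply(names(reports), function(id) {
      r <- reports[[id]]
      data.frame(id = id, pct_bad_channels_all = r$pct_bad_channels_all,
                 pct_bad_channels_1020 = r$pct_bad_channels_1020,
                 pct_bad_epochs = r$pct_bad_epochs,
                 n_components_removed = r$n_components_removed,
                 clean_signal_length = r$clean_signal_length)
    }))
    if (!is.null(cleaning)) {
      utils::write.csv(cleaning, file.path(out_dir, "cleaning_reports.csv"),
                       row.names = FALSE)
    }
  }
  if (length(inputs) == 0) stop("all recordings were quarantined")

  result <- list(cleaning = cleaning, quarantine = quarantine)
  if (isTRUE(config$stages$measures)) {
    hm <- headline_measures(inputs, config,
                            min_length_s = config$preprocess$min_clean_s)
    result$measures <- hm
    utils::write.csv(hm$summaries, file.path(out_dir, "subject_measures.csv"),
                     row.names = FALSE)
  }
  if (isTRUE(config$stages$stats) && !is.null(result$measures)) {
    sm <- result$measures$summaries
    if (length(unique(stats::na.omit(sm$group))) == 2) {
      stats_tab <- do.call(rbind, lapply(
        c("delta_power", "dfa", "fei", "exponent"), function(m) {
          r <- ancova_group_age(sm[[m]], sm$group, sm$age)
          data.frame(measure = m, F = r["F"], p = r["p"],
                     significant = r["p"] < config$stats$alpha,
                     row.names = NULL)
        }))
      result$stats <- stats_tab
      utils::write.csv(stats_tab, file.path(out_dir, "group_stats.csv"),
                       row.names = FALSE)
      el_tests <- lapply(result$measures$electrode, function(v)
        electrode_group_test(v, sm$group, sm$age))
      result$electrode_stats <- el_tests
      for (nm in names(el_tests)) {
        utils::write.csv(el_tests[[nm]],
                         file.path(out_dir, paste0("stats_electrodes_", nm, ".csv")),
                         row.names = FALSE)
      }
    }
  }

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  manifest <- list(
    package = "eispec",
    version = as.character(utils::packageVersion("eispec")),
    config_hash = unname(tools::md5sum(cfg_path)),
    n_recordings = length(recordings),
    n_included = length(inputs),
    quarantined = quarantine)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(result)
}

#' Downsample a recording with anti-alias filtering
#'
#' Polyphase resampling (FIR anti-alias low-pass) to the target rate.
#'
#' @param recording an `eeg_recording`.
#' @param target_rate target sampling rate in Hz (must not exceed the
#'   original).
#' @return The resampled recording.
#' @export
resample_recording <- function(recording, target_rate = 200) {
  fs <- recording$sampling_rate
  if (fs < target_rate) stop("original rate is below the target rate")
  if (fs == target_rate) return(recording)
  g <- gcd_int(round(fs), round(target_rate))
  p <- round(target_rate) / g
  q <- round(fs) / g
  if (p == 1) {
    # integer decimation: zero-phase FIR anti-alias filter, then subsample
    cutoff <- 0.8 * target_rate / 2
    kern <- design_fir_lowpass(cutoff, fs, transition_hz = 0.2 * target_rate / 2)
    idx <- seq(1, ncol(recording$signal), by = q)
    sig <- t(apply(recording$signal, 1, function(v)
      fir_apply_zerophase(v, kern)[idx]))
  } else {
    sig <- t(apply(recording$signal, 1, function(v)
      as.numeric(signal::resample(v, p, q))))
  }
  out <- recording
  out$signal <- sig
  rownames(out$signal) <- recording$channel_labels
  out$sampling_rate <- target_rate
  out
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Resampling-robustness check
#'
#' Recomputes spectral power (log10, 1-45 Hz on the 0.125-Hz grid), the
#' DFA and fE/I spectra (1-Hz bins) and the aperiodic exponent on a
#' recording before and after downsampling to a common rate, and reports
#' the Pearson correlation between the paired values for each measure
#' (across electrodes x bins; electrodes only for the exponent). fE/I pairs
#' are restricted to bins valid at both rates.
#'
#' @param recording an `eeg_recording` (original rate >= `target_rate`).
#' @param target_rate common rate in Hz.
#' @param bins analysis bins for DFA/fE/I.
#' @param min_length_s minimum clean length passed to the estimators.
#' @return List with per-measure correlations (`power`, `dfa`, `fei`,
#'   `exponent`) and the paired value matrices.
#' @export
resampling_check <- function(recording, target_rate = 200, bins = 1:44,
                             min_length_s = 100) {
  if (recording_duration(recording) < min_length_s) {
    stop("recording shorter than the ", min_length_s, " s inclusion minimum")
  }
  rec2 <- resample_recording(recording, target_rate)
  p1 <- welch_psd(recording)
  p2 <- welch_psd(rec2)
  sel1 <- p1$frequencies >= 1 & p1$frequencies <= 45
  sel2 <- p2$frequencies >= 1 & p2$frequencies <= 45
  lp1 <- log10(p1$power[, sel1, drop = FALSE])
  lp2 <- log10(p2$power[, sel2, drop = FALSE])
  c1 <- measure_core(list(recording$signal), recording$sampling_rate, bins)
  c2 <- measure_core(list(rec2$signal), rec2$sampling_rate, bins)
  d1 <- list(values = c1$dfa)
  d2 <- list(values = c2$dfa)
  f1 <- list(values = c1$fei, validity = c1$validity$fei)
  f2 <- list(values = c2$fei, validity = c2$validity$fei)
  a1 <- fit_spectral_model(p1)
  a2 <- fit_spectral_model(p2)
  if (inherits(a1, "aperiodic_fit")) { a1 <- list(a1); a2 <- list(a2) }
  e1 <- vapply(a1, function(x) x$exponent, 0)
  e2 <- vapply(a2, function(x) x$exponent, 0)
  both <- f1$validity & f2$validity &
    is.finite(f1$values) & is.finite(f2$values)
  fei_cor <- if (sum(both) >= 3) {
    stats::cor(f1$values[both], f2$values[both])
  } else NA_real_
  list(power = stats::cor(as.vector(lp1), as.vector(lp2)),
       dfa = stats::cor(as.vector(d1$values), as.vector(d2$values)),
       fei = fei_cor,
       exponent = if (length(e1) >= 3) stats::cor(e1, e2) else NA_real_,
       pairs = list(power = cbind(as.vector(lp1), as.vector(lp2)),
                    dfa = cbind(as.vector(d1$values), as.vector(d2$values)),
                    fei = cbind(f1$values[both], f2$values[both]),
                    exponent = cbind(e1, e2)),
       n_fei_valid = sum(both))
}
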