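# The eeg_recording container and its plain-text fixture format.

#' Construct an EEG recording object
#'
#' The package's container for continuous multichannel EEG: a channels x
#' samples matrix in microvolts plus sampling rate, channel labels and
#' subject metadata.
#'
#' @param signal numeric matrix, channels x samples, in microvolts.
#' @param sampling_rate sampling rate in Hz.
#' @param channel_labels character vector, one label per channel (unique).
#' @param subject named list of subject metadata; recognized fields are
#'   `id`, `group` ("control" or "patient"), `age` (years), `site`, and
#'   `clinical_scores` (named numeric values in 1..5).
#' @param reference reference description, `"average"` or an electrode label.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, sampling_rate, channel_labels,
                          subject = list(), reference = "unknown") {
  signal <- as.matrix(signal)
  if (nrow(signal) == 0) stop("recording has zero channels")
  if (anyNA(signal) || any(!is.finite(signal))) stop("signal contains NA or non-finite values")
  if (length(channel_labels) != nrow(signal)) {
    stop("channel_labels length does not match the number of channels")
  }
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  stopifnot(is.numeric(sampling_rate), length(sampling_rate) == 1, sampling_rate > 0)
  rownames(signal) <- channel_labels
  structure(list(signal = signal,
                 sampling_rate = as.numeric(sampling_rate),
                 channel_labels = as.character(channel_labels),
                 subject = subject,
                 reference = reference),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  dur <- ncol(x$signal) / x$sampling_rate
  cat(sprintf("<eeg_recording> %d channels x %.1f s @ %g Hz (ref: %s)\n",
              nrow(x$signal), dur, x$sampling_rate, x$reference))
  if (!is.null(x$subject$id)) {
    cat(sprintf("  subject %s  group=%s  age=%s\n", x$subject$id,
                x$subject$group %||% "?", format(x$subject$age %||% NA)))
  }
  cat("  channels:", paste(utils::head(x$channel_labels, 10), collapse = " "),
      if (length(x$channel_labels) > 10) "..." else "", "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Recording duration in seconds
#' @param recording an `eeg_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(recording) {
  ncol(recording$signal) / recording$sampling_rate
}

#' Write a recording to the plain-text fixture container
#'
#' The fixture container is a pair of files: `<stem>.csv` holding the signal
#' (one column per channel, header = labels, values in microvolts) and
#' `<stem>.json` holding the sampling rate, reference and subject metadata.
#'
#' @param recording an `eeg_recording`.
#' @param stem path stem (without extension) to write to.
#' @param digits number of significant digits kept in the CSV.
#' @return Invisibly, the two file paths written.
#' @export
write_recording <- function(recording, stem, digits = 6) {
  csv <- paste0(stem, ".csv")
  js <- paste0(stem, ".json")
  m <- t(recording$signal)
  mode(m) <- "numeric"
  utils::write.csv(signif(m, digits), csv, row.names = FALSE)
  meta <- list(sampling_rate = recording$sampling_rate,
               channel_labels = recording$channel_labels,
               reference = recording$reference,
               subject = recording$subject)
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}

#' Read a recording from the fixture container
#'
#' Reads the `<stem>.csv` / `<stem>.json` pair written by
#' [write_recording()]. Channel labels are normalized to classic 10-20 names
#' where recognized (T7/T8/P7/P8 become T3/T4/T5/T6).
#'
#' @param stem path stem (without extension), or the `.csv` path itself.
#' @param metadata optional named list merged over the stored subject
#'   metadata (e.g. group or age supplied from a cohort table).
#' @return An `eeg_recording`.
#' @export
read_recording <- function(stem, metadata = NULL) {
  stem <- sub("\\.csv$", "", stem)
  csv <- paste0(stem, ".csv")
  js <- paste0(stem, ".json")
  if (!file.exists(csv)) stop("fixture file not found: ", csv)
  if (!file.exists(js)) stop("fixture sidecar not found: ", js)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  if (is.null(meta$sampling_rate)) stop("sidecar is missing the sampling rate")
  m <- utils::read.csv(csv, check.names = FALSE)
  if (ncol(m) == 0) stop("recording has zero channels")
  subject <- as.list(meta$subject %||% list())
  if (!is.null(metadata)) subject[names(metadata)] <- metadata
  eeg_recording(t(as.matrix(m)), meta$sampling_rate,
                normalize_labels(colnames(m)),
                subject = subject,
                reference = meta$reference %||% "unknown")
}
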