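#' Multichannel EEG recording
#'
#' Container for a multichannel EEG time series. Samples are stored as a
#' numeric matrix with one column per channel (column names are the channel
#' labels, 10-20 system) and one row per time sample, in microvolts.
#'
#' @param samples Numeric matrix, samples x channels. Column names, if
#'   present, must agree with `channel_labels`.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_labels Character vector of unique channel labels. Defaults
#'   to the column names of `samples`.
#' @param artifact_mask Optional logical vector, one element per sample;
#'   `TRUE` marks samples excluded from spectral estimation.
#'
#' @return An object of class `eeg_recording`: a list with elements
#'   `samples`, `fs`, `channel_labels`, `artifact_mask`.
#' @examples
#' rec <- eeg_recording(cbind(F3 = sin(1:100), F4 = cos(1:100)), fs = 100)
#' rec
#' @export
eeg_recording <- function(samples, fs, channel_labels = colnames(samples),
                          artifact_mask = NULL) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (is.null(channel_labels)) {
    stop_invalid("channel_labels", "labels are required (none supplied and samples has no column names)")
  }
  channel_labels <- as.character(channel_labels)
  if (ncol(samples) != length(channel_labels)) {
    stop_invalid("channel_labels", sprintf(
      "%d labels for %d channels", length(channel_labels), ncol(samples)))
  }
  if (anyDuplicated(toupper(channel_labels))) {
    stop_invalid("channel_labels", "labels must be unique")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop_invalid("fs", "sampling rate must be a positive number")
  }
  if (!is.null(artifact_mask)) {
    artifact_mask <- as.logical(artifact_mask)
    if (length(artifact_mask) != nrow(samples)) {
      stop_invalid("artifact_mask", "mask length must equal the number of samples")
    }
  }
  colnames(samples) <- channel_labels
  structure(
    list(samples = samples, fs = fs, channel_labels = channel_labels,
         artifact_mask = artifact_mask),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  n <- nrow(x$samples)
  masked <- if (is.null(x$artifact_mask)) 0L else sum(x$artifact_mask)
  cat(sprintf(
    "<eeg_recording> %d channels (%s), %d samples @ %g Hz (%.1f s), %d masked\n",
    ncol(x$samples), paste(x$channel_labels, collapse = ", "),
    n, x$fs, n / x$fs, masked))
  invisible(x)
}

#' Look up a channel by label (case-insensitive)
#'
#' @param rec An [eeg_recording].
#' @param label Channel label, matched case-insensitively against the 10-20
#'   labels of the recording.
#' @return Numeric vector of samples for that channel.
#' @export
channel_data <- function(rec, label) {
  stopifnot(inherits(rec, "eeg_recording"))
  i <- match(toupper(label), toupper(rec$channel_labels))
  if (is.na(i)) {
    stop(sprintf("channel '%s' not present (have: %s)", label,
                 paste(rec$channel_labels, collapse = ", ")), call. = FALSE)
  }
  rec$samples[, i]
}

#' Read / write the plain-text EEG channel-matrix format
#'
#' The interchange format is a CSV with one column per channel (header row of
#' 10-20 labels) and one sample per row, accompanied by a JSON sidecar
#' `<path>.json` holding the sampling rate and channel labels.
#'
#' @param rec An [eeg_recording].
#' @param path Path to the CSV file; the sidecar is written/read at
#'   `paste0(path, ".json")`.
#' @return `write_eeg_csv` returns `path` invisibly; `read_eeg_csv` returns
#'   an [eeg_recording].
#' @export
write_eeg_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  df <- as.data.frame(rec$samples)
  write.csv(df, path, row.names = FALSE)
  sidecar <- list(fs = rec$fs, channel_labels = rec$channel_labels)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_eeg_csv
#' @export
read_eeg_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  sidecar_path <- paste0(path, ".json")
  df <- read.csv(path, check.names = FALSE)
  if (file.exists(sidecar_path)) {
    meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    fs <- meta$fs
    labels <- meta$channel_labels %||% colnames(df)
  } else {
    stop(sprintf("sampling-rate sidecar not found: %s", sidecar_path),
         call. = FALSE)
  }
  eeg_recording(as.matrix(df), fs = fs, channel_labels = labels)
}
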