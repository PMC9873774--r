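#' Write an EEG recording as a CSV matrix with a JSON sidecar
#'
#' The matrix has rows = samples and columns = channels with the channel
#' labels as header; the sidecar `<path>.json` records the sampling rate
#' and labels.
#'
#' @param recording an [eeg_recording()].
#' @param path output CSV path.
#' @return invisibly, the sidecar path.
#' @export
write_eeg_csv <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  utils::write.csv(as.data.frame(recording$signal), path,
                   row.names = FALSE)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(fs = recording$fs,
                            channel_labels = recording$channel_labels,
                            n_samples = nrow(recording$signal)),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read an EEG recording from a CSV matrix plus JSON sidecar
#'
#' @param path CSV path written by [write_eeg_csv()] (or any delimited
#'   numeric matrix with a header of channel labels).
#' @param fs sampling rate in Hz; taken from the `<path>.json` sidecar
#'   when `NULL`.
#' @param sep field separator ("," default; "\t" for TSV).
#' @return an [eeg_recording()].
#' @export
read_eeg_csv <- function(path, fs = NULL, sep = ",") {
  if (is.null(fs) || is.na(fs)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) {
      stop("no sampling rate given and sidecar not found: ", sidecar)
    }
    fs <- jsonlite::read_json(sidecar)$fs
  }
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         check.names = FALSE)
  eeg_recording(as.matrix(d), fs = fs, channel_labels = colnames(d))
}

#' Write ground-truth blink intervals as a 3-column onset/peak/offset table
#'
#' BED-like plain-text table of sample indices, one row per blink.
#'
#' @param truth data.frame with onset, peak, offset columns.
#' @param path output path (tab-separated).
#' @export
write_blink_truth <- function(truth, path) {
  utils::write.table(truth[, c("onset", "peak", "offset")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write detected blinks and a JSON summary
#'
#' The event table has columns onset_s, peak_s, offset_s, tent_r, pavr;
#' the summary JSON records best_channel, n_blinks and rate_per_min.
#'
#' @param series a `blink_series` from [detect_blinks()].
#' @param path output CSV path for the event table; the summary is
#'   written to `<path>.json`.
#' @export
write_blink_series <- function(series, path) {
  stopifnot(inherits(series, "blink_series"))
  cols <- c("onset_s", "peak_s", "offset_s", "tent_r", "pavr")
  tab <- if (nrow(series$blinks) > 0) {
    series$blinks[, cols]
  } else {
    stats::setNames(as.data.frame(matrix(numeric(0), ncol = 5)), cols)
  }
  utils::write.csv(tab, path, row.names = FALSE)
  jsonlite::write_json(list(best_channel = series$best_channel,
                            n_blinks = nrow(series$blinks),
                            rate_per_min = series$rate),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a per-object category codebook from JSON
#'
#' Expected layout: `{"object": ["category", ...], ...}`.
#'
#' @param path JSON file path.
#' @return named list, object id -> character vector of categories.
#' @export
read_codebook <- function(path) {
  if (!file.exists(path)) stop("codebook file not found: ", path)
  cb <- jsonlite::read_json(path)
  lapply(cb, function(x) unlist(x, use.names = FALSE))
}
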