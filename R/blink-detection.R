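#' Construct an EEG recording object
#'
#' Thin container for a samples x channels numeric matrix with its
#' sampling rate and channel labels.
#'
#' @param signal numeric matrix, rows = samples, columns = channels.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one label per column; defaults
#'   to the matrix column names.
#' @return an object of class `eeg_recording` with fields `signal`, `fs`,
#'   `channel_labels` and `duration` (seconds).
#' @export
eeg_recording <- function(signal, fs, channel_labels = colnames(signal)) {
  signal <- as.matrix(signal)
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("ch%d", seq_len(ncol(signal)))
  }
  stopifnot(is.numeric(signal), fs > 0,
            length(channel_labels) == ncol(signal))
  colnames(signal) <- channel_labels
  structure(list(signal = signal, fs = fs,
                 channel_labels = channel_labels,
                 duration = nrow(signal) / fs),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %.1f s @ %g Hz\n",
              ncol(x$signal), x$duration, x$fs))
  cat("channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Zero-phase band-pass filter an EEG recording
#'
#' Applies a 4th-order Butterworth band-pass (2nd-order design per edge)
#' forward and backward (zero phase) to every channel. The input object is
#' left unchanged.
#'
#' @param recording an [eeg_recording()].
#' @param low,high band edges in Hz (defaults 1 and 20).
#' @return a filtered copy of `recording`.
#' @export
bandpass <- function(recording, low = 1, high = 20) {
  stopifnot(inherits(recording, "eeg_recording"))
  nyq <- recording$fs / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop("band edges must satisfy 0 < low < high < fs/2 (Nyquist = ",
         nyq, " Hz)")
  }
  bf <- signal::butter(2, c(low, high) / nyq, type = "pass")
  out <- recording
  # remove the DC level first: filtfilt starts from zero initial
  # conditions, so a large offset would otherwise leak in as an edge
  # transient
  out$signal <- apply(recording$signal, 2,
                      function(col) signal::filtfilt(bf, col - mean(col)))
  colnames(out$signal) <- recording$channel_labels
  out
}

# Extend a kept above-threshold run outward to the surrounding sub-mean
# samples, i.e. recover the full waveform base around the exceedance.
extend_to_baseline <- function(x, mu, from, to) {
  while (from > 1 && x[from - 1] > mu) from <- from - 1
  n <- length(x)
  while (to < n && x[to + 1] > mu) to <- to + 1
  c(from, to)
}

#' Find blink candidates on a single channel
#'
#' Candidate events are maximal runs where the signal exceeds the overall
#' channel mean plus 1.5 standard deviations (both computed over the whole
#' segment); runs whose above-threshold duration does not exceed
#' `min_duration` are dropped (small rapid eye movements and noise
#' excursions rarely stay above threshold that long). Each surviving run
#' is then extended outward to the surrounding sub-mean samples so that
#' the full waveform base, not only its tip, defines the candidate frame
#' used for scoring. Frames whose gap is below `min_ibi` are pruned
#' keeping the larger amplitude, enforcing the minimal inter-blink
#' interval.
#'
#' @param channel_signal numeric vector (one filtered channel).
#' @param fs sampling rate in Hz.
#' @param threshold_sd threshold in SD units above the mean (default 1.5).
#' @param min_duration minimal event duration in seconds (default 0.05).
#' @param min_ibi minimal inter-event gap in seconds (default 0.05).
#' @return data.frame with columns onset, peak, offset (sample indices)
#'   and amplitude (signal units above the channel mean), sorted by onset.
#'   A constant channel yields zero candidates.
#' @export
find_candidates <- function(channel_signal, fs,
                            threshold_sd = 1.5,
                            min_duration = 0.05,
                            min_ibi = 0.05) {
  x <- as.numeric(channel_signal)
  stopifnot(length(x) >= fs)  # at least one second of data
  mu <- mean(x)
  sdev <- stats::sd(x)
  empty <- data.frame(onset = integer(0), peak = integer(0),
                      offset = integer(0), amplitude = numeric(0))
  if (!is.finite(sdev) || sdev == 0) return(empty)
  above <- x > mu + threshold_sd * sdev
  if (!any(above)) return(empty)

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  # duration rule on the above-threshold run itself
  runs <- runs[(runs[, 2] - runs[, 1]) / fs > min_duration, ,
               drop = FALSE]
  if (nrow(runs) == 0) return(empty)

  frames <- t(apply(runs, 1, function(rw)
    extend_to_baseline(x, mu, rw[1], rw[2])))
  # extension can make neighbouring frames touch; collapse duplicates
  frames <- unique(frames)
  keep <- c(TRUE, diff(frames[, 1]) > 0 | diff(frames[, 2]) > 0)
  frames <- frames[keep, , drop = FALSE]
  # merge overlapping frames
  merged <- list(frames[1, ])
  if (nrow(frames) > 1) {
    for (i in 2:nrow(frames)) {
      last <- merged[[length(merged)]]
      if (frames[i, 1] <= last[2]) {
        merged[[length(merged)]] <- c(last[1], max(last[2], frames[i, 2]))
      } else {
        merged[[length(merged) + 1]] <- frames[i, ]
      }
    }
  }
  frames <- do.call(rbind, merged)

  cand <- do.call(rbind, lapply(seq_len(nrow(frames)), function(i) {
    on <- frames[i, 1]; off <- frames[i, 2]
    pk <- on + which.max(x[on:off]) - 1L
    data.frame(onset = on, peak = pk, offset = off,
               amplitude = x[pk] - mu)
  }))
  # enforce minimal inter-event interval: drop the smaller of any pair
  # closer than min_ibi, repeating until stable
  repeat {
    if (nrow(cand) < 2) break
    gaps <- cand$onset[-1] - cand$offset[-nrow(cand)]
    tight <- which(gaps < min_ibi * fs)
    if (length(tight) == 0) break
    i <- tight[1]
    drop <- if (cand$amplitude[i] >= cand$amplitude[i + 1]) i + 1 else i
    cand <- cand[-drop, , drop = FALSE]
  }
  rownames(cand) <- NULL
  cand
}

#' Score a blink candidate: tent-shape correlation and pAVR
#'
#' `tent_r` is the Pearson correlation between the candidate segment and a
#' two-piece linear tent anchored at the candidate's onset, peak and
#' offset samples (rising 0 to 1, falling 1 to 0); an exact triangular
#' waveform scores 1. `pavr` is the positive amplitude-velocity ratio,
#' 100 x (peak amplitude above the local baseline) / (maximum rising-limb
#' velocity in units per second); step-like saccades, whose velocity is
#' large relative to their amplitude, score low. The local baseline is the
#' mean of the 100 ms windows flanking the candidate frame.
#'
#' @param candidate one-row data.frame (or list) with onset, peak, offset.
#' @param channel_signal the filtered channel the candidate came from.
#' @param fs sampling rate in Hz.
#' @return the candidate with `tent_r`, `pavr` and a logical `degenerate`
#'   flag (segments of fewer than 3 samples cannot be scored and are
#'   marked rejected).
#' @export
score_candidate <- function(candidate, channel_signal, fs) {
  x <- as.numeric(channel_signal)
  on <- candidate$onset; pk <- candidate$peak; off <- candidate$offset
  stopifnot(on >= 1, off <= length(x), on <= pk, pk <= off)
  out <- as.data.frame(candidate)
  if (off - on + 1 < 3 || pk == on) {
    out$tent_r <- NA_real_; out$pavr <- NA_real_; out$degenerate <- TRUE
    return(out)
  }
  seg <- x[on:off]
  tent <- c(seq(0, 1, length.out = pk - on + 1),
            if (off > pk) seq(1, 0, length.out = off - pk + 1)[-1])
  out$tent_r <- suppressWarnings(stats::cor(seg, tent))

  flank <- round(0.1 * fs)
  pre <- x[max(1, on - flank):max(1, on - 1)]
  post <- x[min(length(x), off + 1):min(length(x), off + flank)]
  baseline <- mean(c(pre, post))
  amp <- x[pk] - baseline
  vel <- max(diff(x[on:pk])) * fs      # units per second, rising limb
  out$pavr <- if (vel > 0) 100 * amp / vel else Inf
  out$degenerate <- FALSE
  out
}

#' Detect blinks in a multichannel EEG recording
#'
#' Full detection chain: zero-phase 1-20 Hz band-pass, per-channel
#' amplitude-threshold candidates, tent-correlation and pAVR scoring, then
#' channel selection. Candidates are accepted when tent_r exceeds
#' `tent_r_min` and pAVR is at least `pavr_min` (low pAVR marks saccades).
#' The best channel is the frontal channel with the most accepted
#' candidates (ties broken by higher median tent_r); the blink rate is
#' computed from that channel only.
#'
#' @param recording an [eeg_recording()]; at least one channel label must
#'   belong to `frontal_set`.
#' @param low,high band-pass edges in Hz.
#' @param threshold_sd candidate threshold in SD units (default 1.5).
#' @param min_duration,min_ibi duration / inter-blink interval floors in
#'   seconds (defaults 0.05).
#' @param tent_r_min minimal tent correlation for acceptance (default 0.90).
#' @param pavr_min minimal pAVR for acceptance; candidates below it are
#'   rejected as saccades (default 3).
#' @param frontal_set labels considered frontal.
#' @return an object of class `blink_series`: list with `blinks` (accepted
#'   candidates on the best channel, with times in seconds), `best_channel`,
#'   `rate` (blinks/min), `duration`, and `per_channel` acceptance counts.
#' @export
detect_blinks <- function(recording, low = 1, high = 20,
                          threshold_sd = 1.5,
                          min_duration = 0.05, min_ibi = 0.05,
                          tent_r_min = 0.90, pavr_min = 3,
                          frontal_set = FRONTAL_CHANNELS) {
  stopifnot(inherits(recording, "eeg_recording"))
  chans <- intersect(recording$channel_labels, frontal_set)
  if (length(chans) == 0) {
    stop("no frontal channel found; expected one of: ",
         paste(frontal_set, collapse = ", "))
  }
  filt <- bandpass(recording, low, high)
  per_channel <- lapply(chans, function(ch) {
    sig <- filt$signal[, ch]
    cand <- find_candidates(sig, filt$fs, threshold_sd,
                            min_duration, min_ibi)
    if (nrow(cand) == 0) {
      return(cbind(cand, tent_r = numeric(0), pavr = numeric(0),
                   degenerate = logical(0), channel = character(0)))
    }
    scored <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i)
      score_candidate(cand[i, ], sig, filt$fs)))
    scored$channel <- ch
    scored[!scored$degenerate &
             scored$tent_r > tent_r_min &
             scored$pavr >= pavr_min, , drop = FALSE]
  })
  names(per_channel) <- chans
  counts <- vapply(per_channel, nrow, integer(1))
  best_set <- which(counts == max(counts))
  if (length(best_set) > 1) {
    med_r <- vapply(per_channel[best_set], function(d)
      if (nrow(d)) stats::median(d$tent_r) else -Inf, numeric(1))
    best_set <- best_set[which.max(med_r)]
  }
  best <- chans[best_set[1]]
  blinks <- per_channel[[best]]
  if (nrow(blinks) > 0) {
    blinks$onset_s <- (blinks$onset - 1) / filt$fs
    blinks$peak_s <- (blinks$peak - 1) / filt$fs
    blinks$offset_s <- (blinks$offset - 1) / filt$fs
  }
  rownames(blinks) <- NULL
  structure(list(blinks = blinks,
                 best_channel = best,
                 rate = blink_rate(nrow(blinks), recording$duration),
                 duration = recording$duration,
                 per_channel_counts = counts),
            class = "blink_series")
}

#' @export
print.blink_series <- function(x, ...) {
  cat(sprintf(
    "<blink_series> %d blinks on %s over %.1f s  (%.2f blinks/min)\n",
    nrow(x$blinks), x$best_channel, x$duration, x$rate))
  invisible(x)
}

#' Blinks per minute
#'
#' @param n_blinks number of accepted blinks (or a `blink_series`).
#' @param duration segment duration in seconds (> 0).
#' @return 60 * count / duration.
#' @export
blink_rate <- function(n_blinks, duration) {
  stopifnot(duration > 0)
  if (inherits(n_blinks, "blink_series")) n_blinks <- nrow(n_blinks$blinks)
  60 * n_blinks / duration
}
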