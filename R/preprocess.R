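# Harmonization and cleaning of raw multichannel recordings.
#
# Multi-site recordings are brought to a common format (target montage
# order, target sampling rate, average reference), notch-filtered for
# power-line interference, band-passed, cut into fixed-length epochs and
# cleaned by peak-amplitude artifact rejection.

#' Harmonize a raw recording to a common format
#'
#' Reorders/subsets channels to `target_montage`, resamples to
#' `target_rate` (anti-alias low-pass followed by linear interpolation onto
#' the new time grid) and applies an average reference.
#'
#' @param rec an `eeg_recording`.
#' @param target_rate target sampling rate, Hz.
#' @param target_montage channel labels defining the output order.
#' @return harmonized `eeg_recording`.
#' @export
harmonize <- function(rec, target_rate = 250,
                      target_montage = default_montage()) {
  stopifnot(inherits(rec, "eeg_recording"))
  idx <- match(target_montage, rec$channels)
  if (anyNA(idx))
    stop("harmonization error: required channel absent: ",
         paste(target_montage[is.na(idx)], collapse = ", "))
  dat <- rec$data[idx, , drop = FALSE]
  fs <- rec$sampling_rate
  if (fs != target_rate) {
    n_in <- ncol(dat)
    n_out <- round(n_in * target_rate / fs)
    if (target_rate < fs) {  # anti-alias before downsampling
      bf <- signal::butter(8, 0.8 * target_rate / fs, type = "low")
      dat <- t(apply(dat, 1, function(x) signal::filtfilt(bf, x)))
    }
    t_in <- (seq_len(n_in) - 1) / fs
    t_out <- (seq_len(n_out) - 1) / target_rate
    dat <- t(apply(dat, 1, function(x)
      approx(t_in, x, xout = pmin(t_out, max(t_in)))$y))
  }
  dat <- sweep(dat, 2, colMeans(dat))   # average reference
  eeg_recording(dat, target_rate, target_montage, rec$subject_id,
                rec$site, rec$timepoint)
}

#' Suppress power-line interference
#'
#' Zero-phase Butterworth band-stop at `line_freq` +/- 2 Hz (applied
#' forwards and backwards, so stop-band attenuation is doubled); the 1-30
#' Hz passband is essentially untouched.
#'
#' @param rec an `eeg_recording`.
#' @param line_freq line frequency, Hz (default 60); must be below Nyquist.
#' @return filtered `eeg_recording`.
#' @export
filter_line_noise <- function(rec, line_freq = 60) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$sampling_rate / 2
  if (line_freq >= nyq)
    stop("configuration error: line_freq must be below Nyquist (", nyq, " Hz)")
  bf <- signal::butter(4, c(line_freq - 2, line_freq + 2) / nyq, type = "stop")
  rec$data <- t(apply(rec$data, 1, function(x) signal::filtfilt(bf, x)))
  rec
}

#' Band-pass filter a recording
#'
#' Zero-phase 4th-order Butterworth band-pass.
#'
#' @param rec an `eeg_recording`.
#' @param lo,hi band edges, Hz; `0 < lo < hi < Nyquist`.
#' @return filtered `eeg_recording`.
#' @export
bandpass <- function(rec, lo = 1, hi = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$sampling_rate / 2
  if (!(lo > 0 && lo < hi && hi < nyq))
    stop("configuration error: need 0 < lo < hi < Nyquist")
  bf <- signal::butter(4, c(lo, hi) / nyq, type = "pass")
  rec$data <- t(apply(rec$data, 1, function(x) signal::filtfilt(bf, x)))
  rec
}

#' Cut a continuous recording into fixed-length epochs
#'
#' Trailing samples that do not fill a whole epoch are discarded.
#'
#' @param rec an `eeg_recording`.
#' @param epoch_length epoch duration, seconds.
#' @return An `epoched_recording`: `data` is epochs x channels x samples.
#' @export
epoch_recording <- function(rec, epoch_length = 2) {
  stopifnot(inherits(rec, "eeg_recording"), epoch_length > 0)
  len <- round(epoch_length * rec$sampling_rate)
  n_ep <- ncol(rec$data) %/% len
  if (n_ep < 1) stop("recording shorter than one epoch")
  arr <- array(NA_real_, c(n_ep, nrow(rec$data), len))
  for (e in seq_len(n_ep))
    arr[e, , ] <- rec$data[, ((e - 1) * len + 1):(e * len)]
  structure(list(data = arr, sampling_rate = rec$sampling_rate,
                 channels = rec$channels, epoch_length = epoch_length,
                 kept_epoch_mask = rep(TRUE, n_ep),
                 subject_id = rec$subject_id, site = rec$site,
                 timepoint = rec$timepoint),
            class = "epoched_recording")
}

#' @export
print.epoched_recording <- function(x, ...) {
  cat(sprintf(
    "<epoched_recording> %s/%s: %d/%d epochs kept, %d ch x %d samples @ %g Hz\n",
    x$subject_id, x$timepoint, sum(x$kept_epoch_mask), dim(x$data)[1],
    dim(x$data)[2], dim(x$data)[3], x$sampling_rate))
  invisible(x)
}

#' Reject epochs by peak amplitude
#'
#' Marks epochs whose absolute amplitude exceeds `peak_threshold` on any
#' channel as rejected (the data are retained; `kept_epoch_mask` tracks
#' usable epochs). Idempotent for a fixed threshold.
#'
#' @param epoched an `epoched_recording`.
#' @param peak_threshold microvolts; `Inf` keeps everything.
#' @param min_epochs minimum surviving epochs before the subject is flagged
#'   unusable.
#' @return `epoched_recording` with updated mask.
#' @export
reject_artifacts <- function(epoched, peak_threshold = 100, min_epochs = 15) {
  stopifnot(inherits(epoched, "epoched_recording"), peak_threshold > 0)
  peak <- apply(abs(epoched$data), 1, max)
  epoched$kept_epoch_mask <- epoched$kept_epoch_mask & (peak <= peak_threshold)
  if (sum(epoched$kept_epoch_mask) < min_epochs)
    stop("quality error: fewer than ", min_epochs,
         " epochs survive artifact rejection for subject ",
         epoched$subject_id)
  epoched
}

#' Kept-epoch data as an array
#' @param epoched an `epoched_recording`.
#' @return epochs x channels x samples array of kept epochs only.
#' @export
kept_epochs <- function(epoched) {
  epoched$data[epoched$kept_epoch_mask, , , drop = FALSE]
}

#' Concatenate kept epochs into one continuous signal per channel
#' @param epoched an `epoched_recording`.
#' @return channels x samples matrix.
#' @export
concatenate_epochs <- function(epoched) {
  arr <- kept_epochs(epoched)
  d <- dim(arr)
  out <- matrix(NA_real_, d[2], d[1] * d[3])
  for (c in seq_len(d[2]))
    out[c, ] <- as.vector(t(arr[, c, ]))
  rownames(out) <- epoched$channels
  out
}

#' Standard preprocessing pipeline for one recording
#'
#' harmonize -> line-noise notch -> band-pass -> epoch -> artifact
#' rejection. Two band-passed copies are produced: 1-30 Hz for spectral and
#' microstate analysis, and a wider 0.5-55 Hz copy for entropy features
#' (sample entropy is sensitive to narrow filtering).
#'
#' @param rec raw `eeg_recording`.
#' @param target_rate Hz (default 250).
#' @param target_montage channel labels.
#' @param line_freq power-line frequency, Hz.
#' @param epoch_length seconds (default 2).
#' @param peak_threshold artifact rejection threshold, microvolts.
#' @param min_epochs minimum usable epochs.
#' @return list with `narrow` (1-30 Hz `epoched_recording`) and `wide`
#'   (0.5-55 Hz `epoched_recording`, same epoch grid and mask).
#' @export
preprocess_recording <- function(rec, target_rate = 250,
                                 target_montage = default_montage(),
                                 line_freq = 60, epoch_length = 2,
                                 peak_threshold = 100, min_epochs = 15) {
  h <- harmonize(rec, target_rate, target_montage)
  h <- filter_line_noise(h, line_freq)
  hi_wide <- min(55, 0.98 * target_rate / 2)
  narrow <- epoch_recording(bandpass(h, 1, 30), epoch_length)
  wide <- epoch_recording(bandpass(h, 0.5, hi_wide), epoch_length)
  narrow <- reject_artifacts(narrow, peak_threshold, min_epochs)
  wide$kept_epoch_mask <- narrow$kept_epoch_mask  # one rejection decision
  list(narrow = narrow, wide = wide)
}
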