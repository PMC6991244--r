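# Electrode-level spectral features: Welch band power per channel and
# left/right lateralization for homologue electrode pairs.

#' Default frequency-band grid
#'
#' Seven non-overlapping bands: delta 1-3.5, theta 4-8, low alpha 8.5-10,
#' high alpha 10.5-12, low beta 12.5-18, middle beta 18.5-21 and high beta
#' 21.5-30 Hz.
#'
#' @return named list of `c(lo, hi)` band edges, Hz.
#' @export
default_band_grid <- function() {
  list(delta = c(1, 3.5), theta = c(4, 8),
       low_alpha = c(8.5, 10), high_alpha = c(10.5, 12),
       low_beta = c(12.5, 18), middle_beta = c(18.5, 21),
       high_beta = c(21.5, 30))
}

#' Welch power spectral density of an epoched recording
#'
#' One Hann-windowed periodogram per kept epoch, averaged over epochs
#' (Welch's method with the epoch grid as non-overlapping segments).
#' Frequency resolution is 1 / epoch_length (0.5 Hz for 2-s epochs).
#'
#' @param epoched an `epoched_recording` with at least one kept epoch.
#' @return list: `freq` (Hz), `power` (channels x frequencies, uV^2/Hz).
#' @export
welch_psd <- function(epoched) {
  stopifnot(inherits(epoched, "epoched_recording"))
  arr <- kept_epochs(epoched)
  if (dim(arr)[1] < 1) stop("quality error: no kept epochs")
  n <- dim(arr)[3]
  fs <- epoched$sampling_rate
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)  # Hann (periodic)
  u <- sum(w^2)                                     # window power norm
  nf <- n %/% 2 + 1
  pow <- matrix(0, dim(arr)[2], nf)
  for (e in seq_len(dim(arr)[1])) {
    seg <- arr[e, , , drop = FALSE][1, , , drop = TRUE]
    if (is.null(dim(seg))) seg <- matrix(seg, nrow = 1)
    seg <- sweep(seg, 1, rowMeans(seg))             # detrend (mean)
    sp <- t(apply(sweep(seg, 2, w, "*"), 1, function(x) {
      X <- fft(x)[seq_len(nf)]
      p <- (Mod(X)^2) / (fs * u)
      # one-sided: double everything except DC and (for even n) Nyquist
      dbl <- rep(2, nf); dbl[1] <- 1
      if (n %% 2 == 0) dbl[nf] <- 1
      p * dbl
    }))
    pow <- pow + sp
  }
  pow <- pow / dim(arr)[1]
  list(freq = seq(0, nf - 1) * fs / n, power = pow,
       channels = epoched$channels)
}

#' Integrated band power from a PSD
#'
#' Trapezoidal integral of the PSD over `[lo, hi]`; additive over a
#' partition of the frequency axis when integrated bin-wise, here computed
#' as the sum of bin powers whose center frequency lies in the band times
#' the bin width (rectangle rule), which makes disjoint bands exactly
#' additive.
#'
#' @param psd result of [welch_psd()].
#' @param band `c(lo, hi)` in Hz, inside the PSD frequency range.
#' @return numeric vector, one non-negative power per channel (uV^2).
#' @export
band_power <- function(psd, band) {
  if (band[1] < min(psd$freq) || band[2] > max(psd$freq))
    stop("configuration error: band outside PSD frequency range")
  df <- psd$freq[2] - psd$freq[1]
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  as.numeric(psd$power[, sel, drop = FALSE] %*% rep(df, sum(sel)))
}

#' Hemispheric lateralization index
#'
#' Normalized difference `(left - right) / (left + right)`, bounded in
#' \[-1, 1\] and scale-free. Undefined (NA) when both sides are zero.
#'
#' @param left_value,right_value non-negative scalars or vectors.
#' @return lateralization index; `NA` where both inputs are zero.
#' @export
lateralization <- function(left_value, right_value) {
  stopifnot(all(left_value >= 0, na.rm = TRUE),
            all(right_value >= 0, na.rm = TRUE))
  tot <- left_value + right_value
  out <- (left_value - right_value) / tot
  out[tot == 0] <- NA_real_
  out
}

#' Electrode-level spectral feature vector for one recording
#'
#' log10 absolute band power for every channel x band, plus the
#' lateralization of (linear) band power for every homologue pair x band.
#'
#' @param epoched an `epoched_recording` (1-30 Hz copy).
#' @param band_grid named list of band edges (default [default_band_grid()]).
#' @return data.frame: class, location, band_or_scale, value.
#' @export
spectral_features <- function(epoched, band_grid = default_band_grid()) {
  psd <- welch_psd(epoched)
  pairs <- homologue_pairs(epoched$channels)
  rows <- list()
  for (b in names(band_grid)) {
    bp <- band_power(psd, band_grid[[b]])
    rows[[length(rows) + 1]] <- data.frame(
      class = "spectral", location = epoched$channels, band_or_scale = b,
      value = log10(pmax(bp, .Machine$double.xmin)),
      stringsAsFactors = FALSE)
    if (nrow(pairs)) {
      li <- lateralization(bp[match(pairs$left, epoched$channels)],
                           bp[match(pairs$right, epoched$channels)])
      rows[[length(rows) + 1]] <- data.frame(
        class = "spectral_asym", location = pairs$pair, band_or_scale = b,
        value = li, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
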