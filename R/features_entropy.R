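# Multiscale entropy: sample entropy of coarse-grained signals over a grid
# of timescales, plus hemispheric entropy asymmetry.
#
# Sample entropy follows the template-counting definition: with tolerance r
# (Chebyshev distance, self-matches excluded), B counts matching template
# pairs of length m and A of length m + 1; SampEn = -ln(A / B). The
# tolerance is fixed from the scale-1 SD of each channel and held constant
# across scales (Costa's convention), making the curve sensitive to how
# signal structure, not variance, changes with scale.

#' Multiscale-entropy configuration
#'
#' @param m template length (default 2).
#' @param r tolerance as a fraction of the scale-1 SD (default 0.15).
#' @param scales number of coarse-graining scales S; entropy is evaluated
#'   at scales 1..S (default 70).
#' @param min_coarse_length minimum coarse-grained length for an entropy
#'   value to be considered valid (default 100).
#' @return list of class `mse_config`.
#' @export
mse_config <- function(m = 2, r = 0.15, scales = 70, min_coarse_length = 100) {
  if (m < 1) stop("configuration error: m must be >= 1")
  if (r <= 0 || r >= 1)
    stop("configuration error: r must be in (0, 1) as a fraction of SD")
  if (scales < 1) stop("configuration error: scales must be >= 1")
  structure(list(m = m, r = r, scales = scales,
                 min_coarse_length = min_coarse_length),
            class = "mse_config")
}

#' Temporal coarse-graining
#'
#' Non-overlapping block means: output element k is the mean of
#' `x[(k-1)*tau + 1 .. k*tau]`; the output length is `floor(length(x)/tau)`.
#'
#' @param x numeric vector.
#' @param tau scale (block length), integer >= 1.
#' @return coarse-grained vector.
#' @export
coarse_grain <- function(x, tau) {
  if (tau < 1 || tau != round(tau))
    stop("configuration error: tau must be a positive integer")
  if (length(x) < tau) stop("signal shorter than one block")
  if (tau == 1) return(x)
  nb <- length(x) %/% tau
  colMeans(matrix(x[seq_len(nb * tau)], nrow = tau))
}

#' Sample entropy
#'
#' `-ln(A/B)` with B the number of template pairs of length `m` within
#' `r_absolute` (Chebyshev distance, self-matches excluded) and A the same
#' count at length `m + 1`. Returns `NA` (never a silent infinity) when
#' either count is zero.
#'
#' @param x numeric vector, length >= m + 2.
#' @param m template length.
#' @param r_absolute absolute tolerance (> 0), same units as `x`.
#' @return non-negative scalar, or `NA` if undefined.
#' @export
sample_entropy <- function(x, m = 2, r_absolute) {
  if (length(x) < m + 2) stop("sequence too short for template length m")
  if (r_absolute <= 0) stop("configuration error: r_absolute must be > 0")
  cnt <- .sampen_counts(as.numeric(x), as.integer(m), as.numeric(r_absolute))
  if (cnt[1] == 0 || cnt[2] == 0) return(NA_real_)
  -log(cnt[1] / cnt[2])
}

#' Multiscale entropy curve for one channel
#'
#' Sample entropy of the coarse-grained signal at every scale 1..S, with
#' the tolerance fixed at `r * sd(x)` of the original (scale-1) signal.
#' Scales whose coarse-grained length falls below `min_coarse_length`
#' are reported as `NA`.
#'
#' @param x numeric vector: concatenated artifact-free signal of one channel.
#' @param config an [mse_config()].
#' @return numeric vector of length `config$scales` (entropy per scale,
#'   `NA` where invalid).
#' @export
mse_curve <- function(x, config = mse_config()) {
  stopifnot(inherits(config, "mse_config"))
  r_abs <- config$r * sd(x)
  if (!is.finite(r_abs) || r_abs == 0)
    stop("quality error: signal has zero or undefined variance")
  out <- rep(NA_real_, config$scales)
  for (tau in seq_len(config$scales)) {
    nb <- length(x) %/% tau
    if (nb < max(config$min_coarse_length, config$m + 2)) next
    out[tau] <- sample_entropy(coarse_grain(x, tau), config$m, r_abs)
  }
  if (all(is.na(out))) stop("quality error: no valid scale for MSE")
  out
}

#' Hemispheric entropy asymmetry
#'
#' Per-scale normalized difference `(L - R) / (L + R)` of two entropy
#' curves on the same scale grid; `NA` wherever either side is missing.
#'
#' @param left_curve,right_curve numeric vectors of equal length.
#' @return numeric vector of per-scale asymmetries.
#' @export
entropy_asymmetry <- function(left_curve, right_curve) {
  stopifnot(length(left_curve) == length(right_curve))
  tot <- left_curve + right_curve
  out <- (left_curve - right_curve) / tot
  out[!is.finite(out)] <- NA_real_
  out
}

#' Multiscale-entropy feature vector for one recording
#'
#' MSE curve per electrode (on the concatenated clean wide-band signal)
#' plus per-scale entropy asymmetry for every homologue pair.
#'
#' @param epoched an `epoched_recording` (wide-band copy).
#' @param config an [mse_config()].
#' @return data.frame: class, location, band_or_scale, value.
#' @export
mse_features <- function(epoched, config = mse_config()) {
  sig <- concatenate_epochs(epoched)
  curves <- t(apply(sig, 1, mse_curve, config = config))
  pairs <- homologue_pairs(epoched$channels)
  rows <- list(data.frame(
    class = "mse",
    location = rep(epoched$channels, each = config$scales),
    band_or_scale = rep(paste0("scale_", seq_len(config$scales)),
                        length(epoched$channels)),
    value = as.vector(t(curves)), stringsAsFactors = FALSE))
  if (nrow(pairs)) {
    asym <- lapply(seq_len(nrow(pairs)), function(i)
      entropy_asymmetry(curves[match(pairs$left[i], epoched$channels), ],
                        curves[match(pairs$right[i], epoched$channels), ]))
    rows[[2]] <- data.frame(
      class = "mse_asym",
      location = rep(pairs$pair, each = config$scales),
      band_or_scale = rep(paste0("scale_", seq_len(config$scales)),
                          nrow(pairs)),
      value = unlist(asym), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
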