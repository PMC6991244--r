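# Microstate segmentation (polarity-invariant modified k-means) and
# derived temporal statistics.
#
# Scalp maps at global-field-power (GFP) peaks are clustered into k
# unit-norm topographies under polarity-invariant assignment (a map and
# its negation belong to the same class). Continuous data are then
# back-fitted sample-by-sample by maximum absolute spatial correlation,
# smoothed by merging segments shorter than a minimum duration, and
# summarized as per-class mean duration, occurrence rate, coverage and the
# segment-level transition probability matrix.

#' Global field power
#'
#' Per-sample standard deviation of the (average-referenced) potential
#' across channels.
#'
#' @param x channels x samples matrix.
#' @return numeric vector, one value per sample.
#' @export
gfp <- function(x) {
  stopifnot(is.matrix(x))
  apply(x, 2, sd)
}

#' Indices of local GFP maxima
#' @param g GFP vector.
#' @return integer vector of interior local-maximum indices.
#' @export
gfp_peaks <- function(g) {
  n <- length(g)
  if (n < 3) return(integer())
  which(g[2:(n - 1)] > g[1:(n - 2)] & g[2:(n - 1)] >= g[3:n]) + 1L
}

# polarity-invariant spatial similarity: squared correlation of centered maps
map_activation <- function(maps, x) {
  # maps: k x C unit-norm (centered); x: C x n centered columns
  crossprod(t(maps), x)  # k x n inner products
}

#' Fit microstate topographies by polarity-invariant modified k-means
#'
#' Clusters GFP-peak maps into `k` unit-norm topographies maximizing global
#' explained variance (GEV) under polarity-invariant assignment; the class
#' topography update is the dominant eigenvector of the assigned maps'
#' outer-product sum. Best of `n_restarts` random initializations is kept.
#'
#' @param peak_maps channels x n_peaks matrix of average-referenced maps
#'   (columns), e.g. recordings sampled at GFP peaks; at least `20 * k`
#'   columns are required.
#' @param k number of microstate classes (default 4, canonical A-D).
#' @param n_restarts random restarts (default 10).
#' @param seed integer seed; the fit is deterministic given the seed.
#' @param max_iter iteration cap per restart.
#' @return list of class `microstate_model`: `maps` (k x channels,
#'   unit-norm rows), `gev`, `k`.
#' @export
fit_microstates <- function(peak_maps, k = 4, n_restarts = 10, seed = 1L,
                            max_iter = 100) {
  stopifnot(is.matrix(peak_maps))
  x <- sweep(peak_maps, 2, colMeans(peak_maps))   # enforce average reference
  n <- ncol(x)
  if (n < 20 * k)
    stop("quality error: need at least ", 20 * k, " GFP-peak maps, got ", n)
  g2 <- colSums(x^2)                               # ~ GFP^2 * (C-1)
  tot <- sum(g2)
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    maps <- t(x[, sample.int(n, k), drop = FALSE])
    maps <- maps / sqrt(rowSums(maps^2))
    lab <- rep(0L, n)
    for (it in seq_len(max_iter)) {
      act <- map_activation(maps, x)               # k x n
      new_lab <- max.col(t(act^2), ties.method = "first")
      if (all(new_lab == lab)) break
      lab <- new_lab
      for (j in seq_len(k)) {
        sel <- lab == j
        if (!any(sel)) {        # dead class: reseed at worst-fit map
          fit <- apply(act^2, 2, max)
          maps[j, ] <- x[, which.min(fit / pmax(g2, 1e-300))]
        } else {
          s <- x[, sel, drop = FALSE]
          ev <- eigen(tcrossprod(s), symmetric = TRUE)
          maps[j, ] <- ev$vectors[, 1]
        }
        maps[j, ] <- maps[j, ] / sqrt(sum(maps[j, ]^2))
      }
    }
    act <- map_activation(maps, x)
    gev <- sum(apply(act^2, 2, max)) / tot
    if (is.null(best) || gev > best$gev)
      best <- list(maps = maps, gev = gev, k = k)
  }
  structure(best, class = "microstate_model")
}

# merge segments shorter than min_len samples into their longer neighbour;
# one sweep relabels every short segment, iterated until stable
smooth_labels <- function(lab, min_len) {
  if (min_len <= 1 || !length(lab)) return(lab)
  for (pass in 1:100) {
    r <- rle(lab)
    ns <- length(r$lengths)
    if (ns == 1) return(lab)
    short <- which(r$lengths < min_len)
    if (!length(short)) return(lab)
    left_len <- c(-1, r$lengths[-ns])
    right_len <- c(r$lengths[-1], -1)
    take_left <- left_len[short] >= right_len[short]
    r$values[short] <- ifelse(take_left,
                              r$values[pmax(short - 1, 1)],
                              r$values[pmin(short + 1, ns)])
    new_lab <- inverse.rle(r)
    if (identical(new_lab, lab)) break  # sweep stalled (oscillation)
    lab <- new_lab
  }
  # resolve any residue one segment at a time (always converges: each
  # merge reduces the segment count)
  repeat {
    r <- rle(lab)
    ns <- length(r$lengths)
    if (ns == 1) break
    short <- which(r$lengths < min_len)
    if (!length(short)) break
    i <- short[which.min(r$lengths[short])]
    left <- if (i > 1) r$lengths[i - 1] else -1
    right <- if (i < ns) r$lengths[i + 1] else -1
    r$values[i] <- if (left >= right) r$values[max(i - 1, 1)]
                   else r$values[i + 1]
    lab <- inverse.rle(r)
  }
  lab
}

#' Back-fit a microstate model and compute temporal statistics
#'
#' Assigns every sample of the recording to the class with maximum absolute
#' spatial correlation, merges segments shorter than `min_duration`, and
#' returns per-class mean duration (ms), occurrence (1/s), coverage
#' (fraction of samples) and the segment-level transition probability
#' matrix (rows sum to 1; diagonal 0 at segment granularity).
#'
#' @param model a `microstate_model`.
#' @param epoched an `epoched_recording` preprocessed as in fitting.
#' @param min_duration minimum segment duration, ms (default 30).
#' @return list: `duration_ms`, `occurrence_hz`, `coverage` (named per
#'   class), `transitions` (k x k matrix), `labels`, `gev`.
#' @export
backfit_microstates <- function(model, epoched, min_duration = 30) {
  stopifnot(inherits(model, "microstate_model"),
            inherits(epoched, "epoched_recording"))
  sig <- concatenate_epochs(epoched)
  sig <- sweep(sig, 2, colMeans(sig))
  fs <- epoched$sampling_rate
  act <- map_activation(model$maps, sig)
  lab <- max.col(t(act^2), ties.method = "first")
  lab <- smooth_labels(lab, max(1L, round(min_duration / 1000 * fs)))
  r <- rle(lab)
  k <- model$k
  total_s <- length(lab) / fs
  dur <- occ <- cov <- setNames(rep(NA_real_, k), paste0("MS", seq_len(k)))
  for (j in seq_len(k)) {
    segs <- r$lengths[r$values == j]
    cov[j] <- sum(segs) / length(lab)
    occ[j] <- length(segs) / total_s
    dur[j] <- if (length(segs)) mean(segs) / fs * 1000 else NA_real_
  }
  trans <- matrix(0, k, k, dimnames = list(paste0("MS", seq_len(k)),
                                           paste0("MS", seq_len(k))))
  if (length(r$values) > 1) {
    for (i in seq_len(length(r$values) - 1))
      trans[r$values[i], r$values[i + 1]] <-
        trans[r$values[i], r$values[i + 1]] + 1
    rs <- rowSums(trans)
    trans[rs > 0, ] <- trans[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  gev <- sum(apply(act^2, 2, max)) / sum(colSums(sig^2))
  list(duration_ms = dur, occurrence_hz = occ, coverage = cov,
       transitions = trans, labels = lab, gev = gev)
}

#' Microstate feature vector for one recording
#'
#' Back-fits `model` and flattens duration/occurrence/coverage and
#' transition probabilities into the standard feature layout.
#'
#' @param epoched an `epoched_recording`.
#' @param model a fitted `microstate_model` (typically group-level).
#' @param min_duration ms.
#' @return data.frame: class, location, band_or_scale, value.
#' @export
microstate_features <- function(epoched, model, min_duration = 30) {
  st <- backfit_microstates(model, epoched, min_duration)
  k <- model$k
  cls <- paste0("MS", seq_len(k))
  base <- data.frame(
    class = "microstate", location = "global",
    band_or_scale = c(paste0("duration_", cls), paste0("occurrence_", cls),
                      paste0("coverage_", cls)),
    value = c(st$duration_ms, st$occurrence_hz, st$coverage),
    stringsAsFactors = FALSE)
  tr <- expand.grid(from = cls, to = cls, stringsAsFactors = FALSE)
  tr <- tr[tr$from != tr$to, ]
  trans <- data.frame(
    class = "microstate", location = "global",
    band_or_scale = paste0("trans_", tr$from, "_", tr$to),
    value = st$transitions[cbind(tr$from, tr$to)],
    stringsAsFactors = FALSE)
  rbind(base, trans)
}

#' Pool GFP-peak maps across recordings for group-level fitting
#'
#' @param epoched_list list of `epoched_recording` objects.
#' @param max_peaks_per_recording cap on peaks sampled per recording.
#' @param seed integer seed for peak subsampling.
#' @return channels x total peaks matrix.
#' @export
pool_gfp_peaks <- function(epoched_list, max_peaks_per_recording = 500,
                           seed = 1L) {
  set.seed(as.integer(seed))
  cols <- lapply(epoched_list, function(ep) {
    sig <- concatenate_epochs(ep)
    sig <- sweep(sig, 2, colMeans(sig))
    pk <- gfp_peaks(gfp(sig))
    if (length(pk) > max_peaks_per_recording)
      pk <- sort(sample(pk, max_peaks_per_recording))
    sig[, pk, drop = FALSE]
  })
  do.call(cbind, cols)
}
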