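# Synthetic multi-site EEG cohorts with known ground-truth group effects.
#
# Each channel is a sum of a 1/f ("pink") background, band-limited
# oscillators (alpha strongest over posterior electrodes) and white sensor
# noise. Group effects are injected either by scaling an oscillator's
# amplitude (band-power effects) or by mixing in an autocorrelated AR(1)
# component (multiscale-entropy effects). Site effects are a per-site gain
# and additive noise floor.

#' Default 10-20 montage
#'
#' Nineteen standard 10-20 electrode labels: eight left/right homologue
#' pairs plus the midline (Fz, Cz, Pz) and no others.
#'
#' @return Character vector of channel labels.
#' @export
default_montage <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6",
    "O1", "O2")
}

#' Left/right homologue pairs of a montage
#'
#' Pairs channels whose labels differ only in an odd (left) versus even
#' (right) terminal digit, e.g. F3/F4, T5/T6. Midline channels (labels
#' ending in "z") are unpaired.
#'
#' @param montage character vector of 10-20 channel labels.
#' @return data.frame with columns `left`, `right`, `pair` (e.g. "F3/F4").
#' @export
homologue_pairs <- function(montage) {
  num <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", montage)))
  stem <- sub("[0-9]+$", "", montage)
  left <- which(!is.na(num) & num %% 2 == 1)
  out <- list()
  for (i in left) {
    # right homologue: same stem, digit + 1 (Fp1->Fp2, T3->T4, T5->T6, ...)
    j <- which(stem == stem[i] & !is.na(num) & num == num[i] + 1)
    if (length(j) == 1) {
      out[[length(out) + 1]] <- data.frame(
        left = montage[i], right = montage[j],
        pair = paste0(montage[i], "/", montage[j]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(left = character(), right = character(),
                      pair = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Specify a ground-truth group effect for cohort simulation
#'
#' @param feature_class `"band_power"` or `"mse"`.
#' @param band for band-power effects, `c(lo, hi)` in Hz naming the
#'   oscillator to scale.
#' @param scale_range for MSE effects, the coarse-graining scales targeted
#'   (used only for bookkeeping; the AR(1) mix shifts low-scale entropy).
#' @param channels channel labels carrying the effect (subset of the montage).
#' @param timepoints subset of `c("baseline", "week2")`.
#' @param effect_size standardized mean difference (Cohen's d) between
#'   responders and nonresponders on the targeted feature; finite.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(feature_class = c("band_power", "mse"),
                        band = NULL, scale_range = NULL,
                        channels, timepoints = c("baseline", "week2"),
                        effect_size) {
  feature_class <- match.arg(feature_class)
  if (!is.finite(effect_size))
    stop("configuration error: effect_size must be finite")
  if (feature_class == "band_power" &&
      (is.null(band) || length(band) != 2 || band[1] >= band[2]))
    stop("configuration error: band_power effect needs band = c(lo, hi)")
  stopifnot(all(timepoints %in% c("baseline", "week2")))
  structure(list(feature_class = feature_class, band = band,
                 scale_range = scale_range, channels = channels,
                 timepoints = timepoints, effect_size = effect_size),
            class = "effect_spec")
}

#' Cohort simulation configuration
#'
#' Defaults emulate the multicenter study the package models: 122 subjects
#' over four sites (52/45/18/7), ~45% responders, 7 of 122 missing the
#' week-2 recording, MADRS baseline 30.1 (5.8) with percent decreases of
#' 73.3 (16.0) for responders versus 20.4 (21.6) for nonresponders.
#'
#' @param n_subjects total cohort size.
#' @param site_sizes per-site subject counts; must sum to `n_subjects`.
#' @param site_names site labels.
#' @param responder_fraction fraction of responders, strictly in (0, 1).
#' @param week2_missing_fraction fraction of subjects lacking the week-2
#'   recording, in \[0, 1).
#' @param sampling_rate Hz.
#' @param duration seconds per recording.
#' @param montage channel labels (left/right homologues plus optional midline).
#' @param effects list of [effect_spec()] objects.
#' @param site_gain per-site multiplicative amplitude scale.
#' @param site_noise per-site additive white-noise SD (microvolts).
#' @param madrs_model list with `baseline_mean`, `baseline_sd`,
#'   `responder_pct` = c(mean, sd), `nonresponder_pct` = c(mean, sd),
#'   `score_noise_sd` (SD of rater noise added to week-2/week-8 scores,
#'   0 for exact label/group agreement).
#' @param seed integer; the single source of randomness.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 122,
                          site_sizes = c(52, 45, 18, 7),
                          site_names = c("SITE_A", "SITE_B", "SITE_C", "SITE_D"),
                          responder_fraction = 55 / 122,
                          week2_missing_fraction = 7 / 122,
                          sampling_rate = 250,
                          duration = 60,
                          montage = default_montage(),
                          effects = list(),
                          site_gain = rep(1, length(site_sizes)),
                          site_noise = rep(1, length(site_sizes)),
                          madrs_model = list(baseline_mean = 30.1,
                                             baseline_sd = 5.8,
                                             responder_pct = c(73.3, 16.0),
                                             nonresponder_pct = c(20.4, 21.6),
                                             score_noise_sd = 0),
                          seed = 1L) {
  if (sum(site_sizes) != n_subjects)
    stop("configuration error: site_sizes must sum to n_subjects")
  if (responder_fraction <= 0 || responder_fraction >= 1)
    stop("configuration error: responder_fraction must be in (0, 1)")
  if (week2_missing_fraction < 0 || week2_missing_fraction >= 1)
    stop("configuration error: week2_missing_fraction must be in [0, 1)")
  if (length(site_names) != length(site_sizes))
    stop("configuration error: site_names/site_sizes length mismatch")
  pairs <- homologue_pairs(montage)
  lonely <- setdiff(grep("[13579]$", montage, value = TRUE), pairs$left)
  if (length(lonely))
    stop("configuration error: left channel(s) without right homologue: ",
         paste(lonely, collapse = ", "))
  for (e in effects) {
    if (!inherits(e, "effect_spec"))
      stop("configuration error: effects must be effect_spec objects")
    if (!all(e$channels %in% montage))
      stop("configuration error: effect channels outside montage")
  }
  structure(list(n_subjects = n_subjects, site_sizes = site_sizes,
                 site_names = site_names,
                 responder_fraction = responder_fraction,
                 week2_missing_fraction = week2_missing_fraction,
                 sampling_rate = sampling_rate, duration = duration,
                 montage = montage, effects = effects,
                 site_gain = site_gain, site_noise = site_noise,
                 madrs_model = madrs_model, seed = as.integer(seed)),
            class = "cohort_config")
}

# 1/f^(beta/2) amplitude-shaped Gaussian noise via FFT coloring.
pink_noise <- function(n, beta = 1) {
  w <- rnorm(n)
  W <- fft(w)
  f <- c(1, seq_len(n - 1))               # avoid f = 0
  f <- pmin(f, n - f + 1)                 # two-sided frequency index
  W <- W * f^(-beta / 2)
  x <- Re(fft(W, inverse = TRUE)) / n
  x / sd(x)
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

# Default oscillator bank: (band lo-hi, base log10-amplitude by scalp region).
# Alpha is strongest posteriorly; theta frontal midline; beta central.
default_oscillators <- function() {
  list(
    list(name = "theta", band = c(4, 8),      amp = 1.2, region = "frontal"),
    list(name = "alpha", band = c(8.5, 12),   amp = 2.5, region = "posterior"),
    list(name = "beta",  band = c(12.5, 21),  amp = 0.8, region = "central")
  )
}

region_weight <- function(channel, region) {
  posterior <- grepl("^(P|O|T5|T6)", channel)
  frontal <- grepl("^(F|Fp)", channel)
  switch(region,
         posterior = if (posterior) 1 else 0.4,
         frontal = if (frontal) 1 else 0.5,
         central = if (grepl("^(C|T3|T4)", channel)) 1 else 0.6,
         1)
}

# Band-limited oscillator: narrowband noise (sinusoid with slow random
# amplitude/frequency modulation), unit RMS.
oscillator_signal <- function(n, fs, band) {
  f0 <- runif(1, band[1], band[2])
  t <- seq_len(n) / fs
  # slow amplitude modulation so the rhythm waxes and wanes
  am <- 1 + 0.3 * sin(2 * pi * runif(1, 0.05, 0.2) * t + runif(1, 0, 2 * pi))
  x <- am * sin(2 * pi * f0 * t + runif(1, 0, 2 * pi))
  x / sd(x)
}

#' Generate a synthetic multi-site EEG cohort
#'
#' Produces raw continuous recordings (one per subject at baseline; a
#' week-2 recording for all but `week2_missing_fraction` of subjects) and a
#' clinical table whose MADRS trajectories reproduce the intended
#' responder/nonresponder assignment under the >= 50% decrease rule.
#' Week-2 signals reuse each subject's latent amplitude parameters with
#' fresh noise plus any week-2-specific effects, so "early change" features
#' have a known ground truth. All randomness flows from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return list with `recordings` (list with elements `baseline`, `week2`;
#'   each a named list of `eeg_recording` objects keyed by subject id) and
#'   `clinical` (data.frame: subject_id, site, age, sex, madrs_baseline,
#'   madrs_week2, madrs_week8, true_group).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  fs <- config$sampling_rate
  nsamp <- round(config$duration * fs)
  montage <- config$montage
  nch <- length(montage)

  site <- rep(config$site_names, times = config$site_sizes)
  n_resp <- round(config$responder_fraction * n)
  group <- rep("nonresponder", n)
  group[sample.int(n, n_resp)] <- "responder"

  mm <- config$madrs_model
  base <- round(rtruncnorm1(n, mm$baseline_mean, mm$baseline_sd, 12, 50))
  pct <- numeric(n)
  is_resp <- group == "responder"
  pct[is_resp] <- rtruncnorm1(sum(is_resp), mm$responder_pct[1],
                              mm$responder_pct[2], 50, 100)
  pct[!is_resp] <- rtruncnorm1(sum(!is_resp), mm$nonresponder_pct[1],
                               mm$nonresponder_pct[2], -60, 49.999)
  noise_sd <- if (is.null(mm$score_noise_sd)) 0 else mm$score_noise_sd
  week8 <- pmax(0, pmin(60, base * (1 - pct / 100) +
                          if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0))
  week8 <- round(week8, 1)
  # week-2 score: partway along the trajectory, with extra spread
  week2 <- pmax(0, pmin(60, base * (1 - 0.45 * pct / 100) + rnorm(n, 0, 3)))
  week2 <- round(week2, 1)

  n_w2 <- round((1 - config$week2_missing_fraction) * n)
  has_w2 <- seq_len(n) %in% sample.int(n, n_w2)

  ids <- sprintf("S%03d", seq_len(n))
  clinical <- data.frame(
    subject_id = ids, site = site,
    age = round(rtruncnorm1(n, 36.3, 12.7, 18, 60)),
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.62, 0.38)),
    madrs_baseline = base, madrs_week2 = week2, madrs_week8 = week8,
    true_group = group, stringsAsFactors = FALSE)

  osc <- default_oscillators()
  site_idx <- match(site, config$site_names)

  # subject-level latent log10 amplitudes per oscillator x channel
  baseline_rec <- vector("list", n)
  week2_rec <- vector("list", n)
  for (s in seq_len(n)) {
    lat <- lapply(osc, function(o) {
      # between-subject SD 0.2 on the log10 amplitude scale
      o$amp * vapply(montage, region_weight, 0, region = o$region) *
        10^rnorm(1, 0, 0.2)
    })
    for (tp in c("baseline", "week2")) {
      if (tp == "week2" && !has_w2[s]) next
      amps <- lat
      ar_mix <- rep(0, nch)
      for (e in config$effects) {
        if (!(tp %in% e$timepoints)) next
        chi <- match(e$channels, montage)
        if (e$feature_class == "band_power") {
          oi <- which(vapply(osc, function(o)
            e$band[1] >= o$band[1] && e$band[2] <= o$band[2], TRUE))[1]
          if (is.na(oi)) oi <- 1
          # d on the log band-power feature ~ d * (2 * 0.2) shift of log10 amp
          if (is_resp[s])
            amps[[oi]][chi] <- amps[[oi]][chi] * 10^(e$effect_size * 0.2)
        } else {
          if (is_resp[s])
            ar_mix[chi] <- ar_mix[chi] + 0.5 * e$effect_size
        }
      }
      dat <- matrix(0, nch, nsamp)
      for (c in seq_len(nch)) {
        x <- 3 * pink_noise(nsamp)
        for (oi in seq_along(osc))
          x <- x + amps[[oi]][c] * oscillator_signal(nsamp, fs, osc[[oi]]$band)
        x <- x + 0.5 * rnorm(nsamp)
        if (ar_mix[c] > 0) {
          # autocorrelated component lowers low-scale sample entropy
          ar <- as.numeric(stats::filter(rnorm(nsamp), 0.95, "recursive"))
          x <- (x + ar_mix[c] * sd(x) * ar / sd(ar)) / sqrt(1 + ar_mix[c]^2)
        }
        dat[c, ] <- x
      }
      dat <- dat * config$site_gain[site_idx[s]] +
        config$site_noise[site_idx[s]] * matrix(rnorm(nch * nsamp), nch)
      rec <- eeg_recording(dat, fs, montage, subject_id = ids[s],
                           site = site[s], timepoint = tp)
      if (tp == "baseline") baseline_rec[[s]] <- rec else week2_rec[[s]] <- rec
    }
  }
  names(baseline_rec) <- ids
  week2_rec <- week2_rec[has_w2]
  names(week2_rec) <- ids[has_w2]
  list(recordings = list(baseline = baseline_rec, week2 = week2_rec),
       clinical = clinical,
       config = config)
}

#' Continuous multichannel EEG recording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param sampling_rate Hz.
#' @param channels channel labels, one per row of `data`.
#' @param subject_id,site,timepoint metadata strings.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sampling_rate, channels,
                          subject_id = NA_character_, site = NA_character_,
                          timepoint = NA_character_) {
  stopifnot(is.matrix(data), nrow(data) == length(channels))
  structure(list(data = data, sampling_rate = sampling_rate,
                 channels = channels, subject_id = subject_id,
                 site = site, timepoint = timepoint),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s/%s: %d ch x %d samples @ %g Hz (site %s)\n",
              x$subject_id, x$timepoint, nrow(x$data), ncol(x$data),
              x$sampling_rate, x$site))
  invisible(x)
}

#' Generate a synthetic leadfield for source analysis
#'
#' Random-geometry gain matrix: sources on a unit sphere projected to
#' channel positions with distance-based attenuation, then
#' average-referenced (columns sum to zero) and column-normalized.
#' Sources are partitioned into `n_rois` contiguous regions.
#'
#' @param n_channels number of electrodes (>= 4).
#' @param n_sources number of sources (>= n_channels).
#' @param seed integer seed.
#' @param n_rois number of named regions partitioning the sources.
#' @return list of class `leadfield`: `gain` (channels x sources), `roi`
#'   (data.frame source_id, roi_label).
#' @export
generate_leadfield <- function(n_channels, n_sources, seed = 1L, n_rois = 8) {
  if (n_channels < 4) stop("configuration error: n_channels must be >= 4")
  if (n_sources < n_channels)
    stop("configuration error: n_sources must be >= n_channels")
  set.seed(as.integer(seed))
  # electrodes on upper hemisphere, sources inside the sphere
  el <- matrix(rnorm(3 * n_channels), ncol = 3)
  el <- el / sqrt(rowSums(el^2)); el[, 3] <- abs(el[, 3])
  src <- matrix(rnorm(3 * n_sources), ncol = 3)
  src <- 0.8 * src / sqrt(rowSums(src^2)) * runif(n_sources, 0.3, 1)^(1 / 3)
  gain <- matrix(0, n_channels, n_sources)
  for (j in seq_len(n_sources)) {
    d2 <- rowSums((el - matrix(src[j, ], n_channels, 3, byrow = TRUE))^2)
    gain[, j] <- 1 / (d2 + 0.1)
  }
  gain <- gain + 0.01 * matrix(rnorm(length(gain)), n_channels)
  gain <- sweep(gain, 2, colMeans(gain))          # average reference
  gain <- sweep(gain, 2, sqrt(colSums(gain^2)), "/")
  roi <- data.frame(
    source_id = seq_len(n_sources),
    roi_label = paste0("ROI_", (seq_len(n_sources) - 1) %/%
                         ceiling(n_sources / n_rois) + 1),
    stringsAsFactors = FALSE)
  structure(list(gain = gain, roi = roi, reference = "average"),
            class = "leadfield")
}

#' Simulate a feature-level two-class cohort
#'
#' Direct simulation of a subjects x features table with a known number of
#' informative features at a specified standardized effect size, bypassing
#' signal synthesis. Used for calibration and power studies of the ranking
#' and classification stages at realistic cohort sizes.
#'
#' @param n subjects (split across `sites` evenly by default).
#' @param n_features total feature count.
#' @param n_informative number of features carrying the effect.
#' @param d Cohen's d of each informative feature.
#' @param responder_fraction class balance.
#' @param site_sizes optional per-site counts summing to `n`.
#' @param seed integer seed.
#' @return list: `x` (n x p matrix), `labels` (factor responder /
#'   nonresponder), `sites`, `informative` (column indices carrying signal).
#' @export
simulate_feature_cohort <- function(n = 120, n_features = 200,
                                    n_informative = 20, d = 1.5,
                                    responder_fraction = 0.5,
                                    site_sizes = NULL, seed = 1L) {
  set.seed(as.integer(seed))
  if (is.null(site_sizes)) {
    nsite <- 4
    site_sizes <- rep(n %/% nsite, nsite)
    site_sizes[1] <- site_sizes[1] + n %% nsite
  }
  stopifnot(sum(site_sizes) == n)
  sites <- rep(paste0("SITE_", seq_along(site_sizes)), times = site_sizes)
  n_resp <- round(responder_fraction * n)
  labels <- rep("nonresponder", n)
  labels[sample.int(n, n_resp)] <- "responder"
  x <- matrix(rnorm(n * n_features), n, n_features)
  informative <- seq_len(min(n_informative, n_features))
  x[labels == "responder", informative] <-
    x[labels == "responder", informative] + d
  colnames(x) <- sprintf("feat_%03d", seq_len(n_features))
  list(x = x, labels = factor(labels, c("nonresponder", "responder")),
       sites = sites, informative = informative)
}

#' Write a cohort to disk as plain-text artifacts
#'
#' Clinical table as CSV, each recording as a headerless sample x channel
#' text matrix, and a JSON manifest recording the configuration and seed.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  for (tp in names(cohort$recordings)) {
    for (rec in cohort$recordings[[tp]]) {
      f <- file.path(dir, sprintf("%s_%s.txt", rec$subject_id, tp))
      write.table(t(rec$data), f, row.names = FALSE,
                  col.names = rec$channels)
    }
  }
  cfg <- cohort$config
  cfg$effects <- lapply(cfg$effects, unclass)
  jsonlite::write_json(unclass(cfg), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
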