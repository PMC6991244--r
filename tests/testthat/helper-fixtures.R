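# Shared fixture builders and independent oracles for the test suite.

# brute-force O(n^2) sample-entropy oracle (template counting, Chebyshev)
sampen_bruteforce <- function(x, m, r) {
  n <- length(x)
  A <- 0; B <- 0
  for (i in 1:(n - m)) {
    for (j in 1:(n - m)) {
      if (j <= i) next
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# small raw recording: named channels, optional pure sinusoid per channel
make_sine_recording <- function(freqs, fs = 250, duration = 20,
                                channels = NULL, noise_sd = 0,
                                amplitude = 1, seed = 1) {
  set.seed(seed)
  n <- round(fs * duration)
  t <- seq_len(n) / fs
  if (is.null(channels)) channels <- paste0("CH", seq_along(freqs))
  dat <- t(vapply(freqs, function(f)
    amplitude * sin(2 * pi * f * t) + rnorm(n, 0, noise_sd),
    numeric(n)))
  eeg_recording(dat, fs, channels, subject_id = "T01", site = "X",
                timepoint = "baseline")
}

# tiny EEG cohort config for fast end-to-end runs
tiny_cohort_config <- function(n = 8, duration = 6, seed = 1,
                               effects = list(), montage = c("F3", "F4",
                                                             "P3", "P4"),
                               week2_missing_fraction = 0) {
  sizes <- c(ceiling(n / 2), floor(n / 2))
  cohort_config(
    n_subjects = n, site_sizes = sizes, site_names = c("A", "B"),
    responder_fraction = 0.5,
    week2_missing_fraction = week2_missing_fraction,
    sampling_rate = 250, duration = duration, montage = montage,
    effects = effects, site_gain = c(1, 1), site_noise = c(1, 1),
    seed = seed)
}

# clinical table with exact responder counts per site: responders get a
# 2/3 decrease, nonresponders 1/3
make_clinical_table <- function(site_sizes, responders_per_site,
                                site_names = names(site_sizes)) {
  if (is.null(site_names)) site_names <- paste0("S", seq_along(site_sizes))
  rows <- list()
  id <- 0
  for (k in seq_along(site_sizes)) {
    for (i in seq_len(site_sizes[k])) {
      id <- id + 1
      resp <- i <= responders_per_site[k]
      rows[[id]] <- data.frame(
        subject_id = sprintf("S%03d", id), site = site_names[k],
        age = 35, sex = "F", madrs_baseline = 30,
        madrs_week2 = 25, madrs_week8 = if (resp) 10 else 20,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
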