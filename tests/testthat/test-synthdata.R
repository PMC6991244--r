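test_that("cohort generation honours subject, site and week-2 counts", {
  cfg <- cohort_config(n_subjects = 122, site_sizes = c(52, 45, 18, 7),
                       week2_missing_fraction = 7 / 122,
                       sampling_rate = 100, duration = 2,
                       montage = c("F3", "F4"), seed = 4)
  coh <- generate_cohort(cfg)
  expect_length(coh$recordings$baseline, 122)
  expect_length(coh$recordings$week2, 115)
  expect_equal(unname(table(coh$clinical$site)[cfg$site_names]),
               c(52, 45, 18, 7), ignore_attr = TRUE)
  # week-2 recordings belong to subjects in the clinical table
  expect_true(all(names(coh$recordings$week2) %in%
                    coh$clinical$subject_id))
})

test_that("MADRS trajectories reproduce the intended group assignment", {
  cfg <- tiny_cohort_config(n = 30, duration = 2, seed = 9,
                            montage = c("C3", "C4"))
  coh <- generate_cohort(cfg)
  lab <- label_responder(coh$clinical$madrs_baseline,
                         coh$clinical$madrs_week8)
  expect_equal(as.character(lab), coh$clinical$true_group)
})

test_that("identical seed gives bit-identical signals and clinical table", {
  cfg <- tiny_cohort_config(n = 4, duration = 3, seed = 21)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$recordings$baseline[[1]]$data,
                   b$recordings$baseline[[1]]$data)
  expect_identical(a$recordings$week2[[3]]$data,
                   b$recordings$week2[[3]]$data)
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(n_subjects = 10, site_sizes = c(4, 4)),
               "sum")
  expect_error(cohort_config(responder_fraction = 0), "responder_fraction")
  expect_error(cohort_config(week2_missing_fraction = 1),
               "week2_missing_fraction")
  expect_error(tiny_cohort_config(montage = c("F3", "F4", "C3")),
               "homologue")
  expect_error(effect_spec("band_power", band = c(8, 12),
                           channels = "F3", effect_size = Inf),
               "finite")
  expect_error(
    cohort_config(effects = list(effect_spec(
      "band_power", band = c(8, 12), channels = "XX", effect_size = 1))),
    "outside montage")
})

test_that("with zero injected effects a fixed feature shows only noise", {
  # type-I error of the group comparison on a pre-registered feature
  # (P3 alpha power) across independent seeds: ~1% at alpha = 0.01
  n_sig <- 0
  n_seeds <- 50
  for (s in seq_len(n_seeds)) {
    cfg <- tiny_cohort_config(n = 14, duration = 4, seed = 100 + s,
                              montage = c("P3", "P4"))
    coh <- generate_cohort(cfg)
    feat <- vapply(coh$recordings$baseline, function(r) {
      ep <- epoch_recording(r, 2)
      log10(band_power(welch_psd(ep), c(8.5, 12))[1])
    }, 0)
    p <- t.test(feat[coh$clinical$true_group == "responder"],
                feat[coh$clinical$true_group == "nonresponder"])$p.value
    n_sig <- n_sig + (p < 0.01)
  }
  expect_lte(n_sig, 2)  # >= 96% of seeds non-significant
})

test_that("injected band-power effect is recovered at its effect size", {
  d_target <- 1.2
  cfg <- cohort_config(
    n_subjects = 200, site_sizes = c(100, 100), site_names = c("A", "B"),
    responder_fraction = 0.5, week2_missing_fraction = 0,
    duration = 20, montage = c("P3", "P4", "Pz"),
    effects = list(effect_spec("band_power", band = c(8.5, 12),
                               channels = c("P3", "P4"),
                               timepoints = "baseline",
                               effect_size = d_target)),
    site_gain = c(1, 1), site_noise = c(1, 1), seed = 11)
  coh <- generate_cohort(cfg)
  feat <- vapply(coh$recordings$baseline, function(r) {
    ep <- epoch_recording(harmonize(r, 250, cfg$montage), 2)
    log10(band_power(welch_psd(ep), c(8.5, 12))[1])
  }, 0)
  g <- coh$clinical$true_group
  d_emp <- (mean(feat[g == "responder"]) - mean(feat[g == "nonresponder"])) /
    sqrt((var(feat[g == "responder"]) + var(feat[g == "nonresponder"])) / 2)
  expect_lt(abs(d_emp - d_target), 0.3)
})

test_that("synthetic leadfield is average-referenced, normalized, rank C-1", {
  lf <- generate_leadfield(20, 200, seed = 5)
  expect_equal(dim(lf$gain), c(20, 200))
  expect_lt(max(abs(colSums(lf$gain))), 1e-10)
  expect_equal(sqrt(colSums(lf$gain^2)), rep(1, 200), tolerance = 1e-12)
  expect_equal(qr(lf$gain)$rank, 19)  # average reference removes one dim
  expect_error(generate_leadfield(20, 10), "n_sources")
  expect_error(generate_leadfield(2, 10), "n_channels")
})

test_that("cohort export writes clinical CSV, recordings and manifest", {
  cfg <- tiny_cohort_config(n = 2, duration = 1, seed = 3)
  coh <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "clinical.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_length(list.files(dir, pattern = "_baseline\\.txt$"), 2)
  reread <- read_clinical(file.path(dir, "clinical.csv"))
  expect_equal(reread$madrs_week8, coh$clinical$madrs_week8)
})
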