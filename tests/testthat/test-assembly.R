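# feature-level fixtures: aligned per-subject tables without signal synthesis
make_feature_tables <- function(ids, values_by_subject) {
  lapply(setNames(ids, ids), function(id) {
    v <- values_by_subject[[id]]
    data.frame(class = "spectral", location = paste0("F", seq_along(v)),
               band_or_scale = "theta", value = v,
               stringsAsFactors = FALSE)
  })
}

make_two_timepoint_fms <- function(n_base = 122, n_w2 = 115, p = 3,
                                   seed = 1) {
  set.seed(seed)
  ids <- sprintf("S%03d", seq_len(n_base))
  clin <- make_clinical_table(n_base, round(n_base * 0.45), "X")
  base_vals <- setNames(lapply(ids, function(i) rnorm(p)), ids)
  w2_ids <- ids[seq_len(n_w2)]
  w2_vals <- setNames(lapply(w2_ids, function(i) rnorm(p)), w2_ids)
  list(
    baseline = feature_matrix(make_feature_tables(ids, base_vals), clin,
                              "baseline"),
    week2 = feature_matrix(make_feature_tables(w2_ids, w2_vals), clin,
                           "week2"))
}

test_that("feature sources have the documented subject counts", {
  fms <- make_two_timepoint_fms()
  expect_equal(nrow(build_source(fms$baseline, fms$week2,
                                 "baseline")$values), 122)
  expect_equal(nrow(build_source(fms$baseline, fms$week2,
                                 "week2")$values), 115)
  expect_equal(nrow(build_source(fms$baseline, fms$week2,
                                 "early_change")$values), 115)
  expect_equal(nrow(build_source(fms$baseline, fms$week2,
                                 "combined")$values), 115)
})

test_that("early change is week2 minus baseline; identical inputs give 0", {
  fms <- make_two_timepoint_fms(n_base = 10, n_w2 = 10)
  ec <- build_source(fms$baseline, fms$week2, "early_change")
  expect_equal(ec$values,
               fms$week2$values - fms$baseline$values,
               ignore_attr = TRUE)
  same <- fms
  same$week2$values[] <- fms$baseline$values
  ec0 <- build_source(same$baseline, same$week2, "early_change")
  expect_true(all(ec0$values == 0))
})

test_that("combined column count is baseline plus early change", {
  fms <- make_two_timepoint_fms(n_base = 20, n_w2 = 18, p = 5)
  comb <- build_source(fms$baseline, fms$week2, "combined")
  expect_equal(ncol(comb$values),
               ncol(fms$baseline$values) +
                 ncol(build_source(fms$baseline, fms$week2,
                                   "early_change")$values))
  expect_false(anyDuplicated(comb$descriptors$key) > 0)
  # source tags separate otherwise-identical descriptors
  expect_setequal(unique(comb$descriptors$source_tag),
                  c("baseline", "early_change"))
})

test_that("assembly is order-independent in the subject dimension", {
  fms <- make_two_timepoint_fms(n_base = 12, n_w2 = 12)
  perm <- sample(12)
  clin <- make_clinical_table(12, 5, "X")
  tabs <- make_feature_tables(fms$week2$subject_id,
                              setNames(lapply(seq_len(12), function(i)
                                fms$week2$values[i, ]),
                                fms$week2$subject_id))
  fm_perm <- feature_matrix(tabs[perm], clin, "week2")
  ec1 <- build_source(fms$baseline, fms$week2, "early_change")
  ec2 <- build_source(fms$baseline, fm_perm, "early_change")
  expect_equal(ec1$values[ec1$subject_id, ],
               ec2$values[ec1$subject_id, ], ignore_attr = TRUE)
})

test_that("misaligned or duplicated descriptors are rejected", {
  clin <- make_clinical_table(2, 1, "X")
  t1 <- data.frame(class = "spectral", location = c("F3", "F3"),
                   band_or_scale = "theta", value = c(1, 2),
                   stringsAsFactors = FALSE)
  expect_error(feature_matrix(list(S001 = t1, S002 = t1), clin),
               "duplicate")
  t2 <- data.frame(class = "spectral", location = c("F3", "F4"),
                   band_or_scale = "theta", value = c(1, 2),
                   stringsAsFactors = FALSE)
  t3 <- t2[2:1, ]
  expect_error(feature_matrix(list(S001 = t2, S002 = t3), clin),
               "not aligned")
})

test_that("feature matrices round-trip to CSV", {
  fms <- make_two_timepoint_fms(n_base = 5, n_w2 = 5)
  vp <- withr::local_tempfile(fileext = ".csv")
  dp <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(fms$baseline, vp, dp)
  vals <- read.csv(vp, check.names = FALSE)
  expect_equal(nrow(vals), 5)
  expect_equal(as.matrix(vals[, -(1:3)]), fms$baseline$values,
               ignore_attr = TRUE)
  desc <- read.csv(dp)
  expect_equal(nrow(desc), ncol(fms$baseline$values))
})
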