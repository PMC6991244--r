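# fast hyperparameter grids for tests; defaults keep the full grids
fast_spec <- function(...) {
  model_spec(C_grid = 2^seq(-3, 7, 2), gamma_grid = 2^seq(-9, 1, 2),
             inner_folds = 3, ...)
}

test_that("balanced accuracy is the mean of sensitivity and specificity", {
  expect_equal(balanced_accuracy(67.3, 91.0), 79.15)
  expect_equal(balanced_accuracy(79.2, 85.5), 82.35)
  expect_equal(balanced_accuracy(64, 64), 64)
  expect_error(balanced_accuracy(-1, 50))
})

test_that("well-separated classes are fit perfectly on training data", {
  fc <- simulate_feature_cohort(100, 5, 5, d = 6, seed = 3)
  sc <- restpredict:::fit_scaler(fc$x)
  xs <- restpredict:::apply_scaler(sc, fc$x)
  m <- train_classifier(xs, fc$labels, fast_spec(T = 0, seed = 3))
  expect_equal(mean(predict(m, xs) == fc$labels), 1)
  expect_error(train_classifier(xs, factor(rep("responder", 100),
                                           levels = levels(fc$labels))),
               "single-class")
})

test_that("duplicated feature columns with halved gamma give the same model", {
  fc <- simulate_feature_cohort(60, 4, 2, d = 1, seed = 5)
  sc <- restpredict:::fit_scaler(fc$x)
  xs <- restpredict:::apply_scaler(sc, fc$x)
  xdup <- cbind(xs, xs)
  s1 <- model_spec(C_grid = 1, gamma_grid = 0.2, inner_folds = 2)
  s2 <- model_spec(C_grid = 1, gamma_grid = 0.1, inner_folds = 2)
  m1 <- train_classifier(xs, fc$labels, s1)
  m2 <- train_classifier(xdup, fc$labels, s2)
  expect_equal(as.character(predict(m1, xs)),
               as.character(predict(m2, xdup)))
})

test_that("null cohorts cross-validate near chance", {
  bas <- vapply(1:3, function(s) {
    fc <- simulate_feature_cohort(120, 30, 0, d = 0, seed = 200 + s)
    cv <- cross_validate(fc$x, fc$labels, fast_spec(T = 0, seed = s),
                         k = 10, nested_ranking = FALSE, seed = s)
    cv$pooled$balanced_accuracy
  }, 0)
  expect_gte(mean(bas), 35)
  expect_lte(mean(bas), 65)
})

test_that("strong effects are learnable through the nested pipeline", {
  fc <- simulate_feature_cohort(60, 40, 10, d = 2, seed = 31)
  cv <- cross_validate(fc$x, fc$labels, fast_spec(T = 60, seed = 31),
                       k = 5, nested_ranking = TRUE, seed = 31)
  expect_gte(cv$pooled$balanced_accuracy, 70)
  # pooled counts equal the sum over folds and match n
  expect_equal(sum(cv$pooled$counts), 60)
  expect_equal(unname(cv$pooled$counts["tp"] + cv$pooled$counts["fn"]),
               sum(fc$labels == "responder"))
  # reported BA is recomputed from counts
  cc <- cv$pooled$counts
  expect_equal(cv$pooled$balanced_accuracy,
               balanced_accuracy(100 * cc["tp"] / (cc["tp"] + cc["fn"]),
                                 100 * cc["tn"] / (cc["tn"] + cc["fp"])),
               ignore_attr = TRUE)
})

test_that("information present only in held-out rows cannot help", {
  # the training rows carry pure noise in every feature; the test rows'
  # first feature encodes the label. A leak-free pipeline stays at chance.
  set.seed(41)
  n_tr <- 60; n_te <- 100
  y_tr <- factor(rep(c("nonresponder", "responder"), n_tr / 2),
                 levels = c("nonresponder", "responder"))
  y_te <- factor(rep(c("nonresponder", "responder"), n_te / 2),
                 levels = c("nonresponder", "responder"))
  x_tr <- matrix(rnorm(n_tr * 5), n_tr,
                 dimnames = list(NULL, paste0("f", 1:5)))
  x_te <- matrix(rnorm(n_te * 5), n_te,
                 dimnames = list(NULL, paste0("f", 1:5)))
  x_te[, 1] <- as.numeric(y_te == "responder")
  res <- restpredict:::fit_and_score(x_tr, y_tr, x_te, y_te,
                                     fast_spec(T = 0, seed = 41),
                                     nested_ranking = FALSE)
  ba <- restpredict:::report_from_counts(res$counts)$balanced_accuracy
  expect_gte(ba, 30)
  expect_lte(ba, 70)
})

test_that("leave-one-site-out reports one row per site and flags degeneracy", {
  fc <- simulate_feature_cohort(80, 30, 10, d = 2, seed = 43,
                                site_sizes = c(30, 30, 20))
  lo <- leave_one_site_out(fc$x, fc$labels, fc$sites,
                           fast_spec(T = 60, seed = 43))
  expect_equal(nrow(lo$per_site), 3)
  expect_equal(sum(lo$per_site$n), 80)
  # force a test site with no responders
  labs <- fc$labels
  labs[fc$sites == "SITE_3"] <- "nonresponder"
  lo2 <- leave_one_site_out(fc$x, labs, fc$sites,
                            fast_spec(T = 60, seed = 43))
  row3 <- lo2$per_site[lo2$per_site$site == "SITE_3", ]
  expect_true(is.na(row3$sensitivity))
  expect_true(is.na(row3$balanced_accuracy))
  expect_match(row3$flag, "lacks a class")
  expect_error(leave_one_site_out(fc$x, fc$labels,
                                  rep("S1", 80), fast_spec()),
               "configuration error")
})

test_that("stratified folds keep both classes in every training part", {
  fc <- simulate_feature_cohort(40, 10, 0, d = 0,
                                responder_fraction = 0.25, seed = 47)
  cv <- cross_validate(fc$x, fc$labels, fast_spec(T = 0, seed = 47),
                       k = 5, nested_ranking = FALSE, seed = 47)
  expect_equal(sum(cv$per_fold$n), 40)
  expect_equal(nrow(cv$per_fold), 5)
})
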