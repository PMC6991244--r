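# RBF-SVM classification with inner-loop hyperparameter search, stratified
# k-fold cross-validation and leave-one-site-out evaluation.
#
# Responder is the positive class throughout. All training-partition
# operations — feature ranking/selection, z-scoring, hyperparameter choice
# — use training subjects only, so held-out subjects never leak into model
# construction.

#' Balanced accuracy from sensitivity and specificity
#'
#' @param sensitivity,specificity percentages in \[0, 100\].
#' @return arithmetic mean, %.
#' @export
balanced_accuracy <- function(sensitivity, specificity) {
  stopifnot(all(sensitivity >= 0 & sensitivity <= 100),
            all(specificity >= 0 & specificity <= 100))
  (sensitivity + specificity) / 2
}

#' RBF-SVM model specification
#'
#' @param C_grid cost grid (default `2^seq(-5, 15, 2)`).
#' @param gamma_grid kernel width grid (default `2^seq(-15, 3, 2)`).
#' @param inner_folds stratified folds of the inner hyperparameter search.
#' @param T vote threshold for feature selection inside each training
#'   partition (one of 50/60/70/80/90 in the standard grids; any value in
#'   \[0, 100\] is allowed).
#' @param n_iterations,fraction,alpha ranking parameters
#'   (see [rank_features()]).
#' @param seed integer seed governing folds, subsampling and the SVM.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(C_grid = 2^seq(-5, 15, 2),
                       gamma_grid = 2^seq(-15, 3, 2),
                       inner_folds = 5, T = 60,
                       n_iterations = 100, fraction = 0.8, alpha = 0.05,
                       seed = 1L) {
  stopifnot(length(C_grid) > 0, length(gamma_grid) > 0, inner_folds >= 2)
  structure(list(C_grid = C_grid, gamma_grid = gamma_grid,
                 inner_folds = inner_folds, T = T,
                 n_iterations = n_iterations, fraction = fraction,
                 alpha = alpha, seed = as.integer(seed)),
            class = "model_spec")
}

# stratified fold assignment: within each class, shuffle and deal into k
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    i <- which(labels == cl)
    fold[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  fold
}

confusion_counts <- function(truth, pred) {
  pos <- "responder"
  c(tp = sum(truth == pos & pred == pos),
    fp = sum(truth != pos & pred == pos),
    tn = sum(truth != pos & pred != pos),
    fn = sum(truth == pos & pred != pos))
}

report_from_counts <- function(cc) {
  sens <- if (cc["tp"] + cc["fn"] > 0)
    100 * cc["tp"] / (cc["tp"] + cc["fn"]) else NA_real_
  spec <- if (cc["tn"] + cc["fp"] > 0)
    100 * cc["tn"] / (cc["tn"] + cc["fp"]) else NA_real_
  ba <- if (is.na(sens) || is.na(spec)) NA_real_
        else balanced_accuracy(sens, spec)
  list(sensitivity = unname(sens), specificity = unname(spec),
       balanced_accuracy = unname(ba), counts = cc)
}

# z-score by training statistics; constant columns scaled by 1
fit_scaler <- function(x) {
  mu <- colMeans(x, na.rm = TRUE)
  sg <- apply(x, 2, sd, na.rm = TRUE)
  sg[!is.finite(sg) | sg == 0] <- 1
  list(mu = mu, sg = sg)
}
apply_scaler <- function(sc, x) sweep(sweep(x, 2, sc$mu), 2, sc$sg, "/")

#' Train an RBF-SVM with inner-loop hyperparameter search
#'
#' Chooses (C, gamma) over the spec's grids by stratified inner
#' cross-validation maximizing balanced accuracy, then refits on all
#' training data with class weights inversely proportional to class
#' frequency. Features are expected to be already selected and z-scored on
#' training statistics (as done by [cross_validate()]).
#'
#' @param x training matrix (subjects x selected features, scaled).
#' @param labels two-level factor.
#' @param spec a [model_spec()].
#' @return list of class `trained_classifier`: `fit` (e1071 svm), `C`,
#'   `gamma`, `inner_ba`.
#' @export
train_classifier <- function(x, labels, spec = model_spec()) {
  labels <- droplevels(factor(labels))
  if (nlevels(labels) != 2) stop("single-class training set")
  cw <- nrow(x) / (2 * table(labels))
  cw <- setNames(as.numeric(cw), names(cw))
  grid <- expand.grid(C = spec$C_grid, gamma = spec$gamma_grid)
  best <- NULL
  if (nrow(grid) > 1) {
    fold <- stratified_folds(labels, spec$inner_folds)
    for (g in seq_len(nrow(grid))) {
      cc <- c(tp = 0, fp = 0, tn = 0, fn = 0)
      for (f in unique(fold)) {
        tr <- fold != f
        if (nlevels(droplevels(labels[tr])) < 2) next
        fit <- e1071::svm(x[tr, , drop = FALSE], labels[tr],
                          kernel = "radial", cost = grid$C[g],
                          gamma = grid$gamma[g], class.weights = cw,
                          scale = FALSE)
        pred <- predict(fit, x[!tr, , drop = FALSE])
        cc <- cc + confusion_counts(labels[!tr], pred)
      }
      ba <- report_from_counts(cc)$balanced_accuracy
      if (is.null(best) || (!is.na(ba) && ba > best$ba))
        best <- list(C = grid$C[g], gamma = grid$gamma[g], ba = ba)
    }
  } else {
    best <- list(C = grid$C[1], gamma = grid$gamma[1], ba = NA_real_)
  }
  fit <- e1071::svm(x, labels, kernel = "radial", cost = best$C,
                    gamma = best$gamma, class.weights = cw, scale = FALSE)
  structure(list(fit = fit, C = best$C, gamma = best$gamma,
                 inner_ba = best$ba),
            class = "trained_classifier")
}

#' @export
predict.trained_classifier <- function(object, newdata, ...) {
  predict(object$fit, newdata)
}

# one training/test evaluation with in-partition ranking + selection
fit_and_score <- function(x_tr, y_tr, x_te, y_te, spec, nested_ranking,
                          precomputed_selection = NULL) {
  sel <- precomputed_selection
  if (is.null(sel)) {
    if (nested_ranking) {
      vt <- rank_features(x_tr, y_tr, spec$n_iterations, spec$fraction,
                          spec$alpha, seed = spec$seed)
      sel <- vt$feature[vt$votes >= spec$T]
      if (!length(sel))  # nothing reaches T in this partition: keep the
        sel <- vt$feature[which.max(vt$votes)]  # top-voted feature
    } else {
      sel <- colnames(x_tr)
    }
  }
  x_tr <- x_tr[, sel, drop = FALSE]
  x_te <- x_te[, sel, drop = FALSE]
  ok_tr <- complete.cases(x_tr)
  ok_te <- complete.cases(x_te)
  sc <- fit_scaler(x_tr[ok_tr, , drop = FALSE])
  model <- train_classifier(apply_scaler(sc, x_tr[ok_tr, , drop = FALSE]),
                            y_tr[ok_tr], spec)
  pred <- predict(model, apply_scaler(sc, x_te[ok_te, , drop = FALSE]))
  list(counts = confusion_counts(y_te[ok_te], pred),
       n_selected = length(sel), n_dropped = sum(!ok_tr) + sum(!ok_te))
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' For each outer fold: rank features on the training part (when
#' `nested_ranking`), select by the spec's vote threshold, z-score by
#' training statistics, tune and train the RBF-SVM, and predict the
#' held-out fold. Confusion counts are pooled over folds.
#'
#' @param x subjects x features matrix or `feature_matrix`.
#' @param labels two-level factor (ignored for `feature_matrix` input).
#' @param spec a [model_spec()].
#' @param k outer folds (default 10).
#' @param nested_ranking recompute ranking inside every training partition
#'   (default TRUE; FALSE reuses a ranking computed on all data — faster
#'   but optimistically biased).
#' @param seed integer seed for the outer fold assignment.
#' @return list of class `eval_report`: `pooled` (sensitivity, specificity,
#'   balanced_accuracy, counts), `per_fold` data.frame, `scheme`.
#' @export
cross_validate <- function(x, labels = NULL, spec = model_spec(), k = 10,
                           nested_ranking = TRUE, seed = 1L) {
  if (inherits(x, "feature_matrix")) {
    labels <- x$label
    x <- x$values
  }
  labels <- droplevels(factor(labels))
  stopifnot(nrow(x) >= 2 * k)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  set.seed(as.integer(seed))
  fold <- stratified_folds(labels, k)
  sel_all <- NULL
  if (!nested_ranking) {
    vt <- rank_features(x, labels, spec$n_iterations, spec$fraction,
                        spec$alpha, seed = spec$seed)
    sel_all <- vt$feature[vt$votes >= spec$T]
    if (!length(sel_all)) sel_all <- vt$feature[which.max(vt$votes)]
  }
  pooled <- c(tp = 0, fp = 0, tn = 0, fn = 0)
  per_fold <- list()
  for (f in sort(unique(fold))) {
    te <- fold == f
    if (nlevels(droplevels(labels[!te])) < 2 ||
        nlevels(droplevels(labels[te])) < 1)
      stop("stratification error: fold without both classes")
    res <- fit_and_score(x[!te, , drop = FALSE], labels[!te],
                         x[te, , drop = FALSE], labels[te],
                         spec, nested_ranking, sel_all)
    pooled <- pooled + res$counts
    rf <- report_from_counts(res$counts)
    per_fold[[f]] <- data.frame(fold = f, n = sum(te),
                                n_selected = res$n_selected,
                                sensitivity = rf$sensitivity,
                                specificity = rf$specificity,
                                balanced_accuracy = rf$balanced_accuracy)
  }
  structure(list(pooled = report_from_counts(pooled),
                 per_fold = do.call(rbind, per_fold),
                 scheme = sprintf("stratified %d-fold (nested_ranking=%s)",
                                  k, nested_ranking)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>", x$scheme, "\n")
  p <- x$pooled
  cat(sprintf("  pooled: BA %.1f%% (sens %.1f%%, spec %.1f%%)\n",
              p$balanced_accuracy, p$sensitivity, p$specificity))
  invisible(x)
}

#' Leave-one-site-out cross-validation
#'
#' Each site in turn forms the test set; ranking, selection, scaling and
#' hyperparameter search are performed on the remaining sites only. Sites
#' whose test set lacks a class get `NA` for the undefined rate and a
#' flagged, non-computable balanced accuracy.
#'
#' @param x subjects x features matrix or `feature_matrix`.
#' @param labels two-level factor (ignored for `feature_matrix` input).
#' @param sites character vector of site labels per subject (taken from a
#'   `feature_matrix` when omitted).
#' @param spec a [model_spec()] (the standard vote threshold here is 60).
#' @return list of class `loso_report`: `per_site` data.frame (site, n,
#'   sensitivity, specificity, balanced_accuracy, flag), `pooled`.
#' @export
leave_one_site_out <- function(x, labels = NULL, sites = NULL,
                               spec = model_spec(T = 60)) {
  if (inherits(x, "feature_matrix")) {
    labels <- x$label
    sites <- x$site
    x <- x$values
  }
  labels <- droplevels(factor(labels))
  if (length(unique(sites)) < 2)
    stop("configuration error: leave-one-site-out needs >= 2 sites")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  set.seed(spec$seed)
  pooled <- c(tp = 0, fp = 0, tn = 0, fn = 0)
  rows <- list()
  for (s in unique(sites)) {
    te <- sites == s
    res <- fit_and_score(x[!te, , drop = FALSE], labels[!te],
                         x[te, , drop = FALSE], labels[te],
                         spec, nested_ranking = TRUE)
    pooled <- pooled + res$counts
    rf <- report_from_counts(res$counts)
    flag <- if (is.na(rf$balanced_accuracy))
      "undefined rate: test site lacks a class" else ""
    rows[[s]] <- data.frame(site = s, n = sum(te),
                            n_selected = res$n_selected,
                            sensitivity = rf$sensitivity,
                            specificity = rf$specificity,
                            balanced_accuracy = rf$balanced_accuracy,
                            flag = flag, stringsAsFactors = FALSE)
  }
  structure(list(per_site = do.call(rbind, rows),
                 pooled = report_from_counts(pooled),
                 scheme = "leave-one-site-out"),
            class = "loso_report")
}

#' @export
print.loso_report <- function(x, ...) {
  cat("<loso_report> leave-one-site-out\n")
  print(x$per_site, row.names = FALSE)
  cat(sprintf("  pooled: BA %.1f%%\n", x$pooled$balanced_accuracy))
  invisible(x)
}
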