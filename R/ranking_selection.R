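# Stability-voting feature ranking: at each of n_iterations, draw a
# class-stratified 80% subsample without replacement, run a Welch
# two-sample two-tailed t test per feature, and give the feature a vote
# when p < alpha. Votes (0..n_iterations) index how robustly a feature
# separates the outcome groups; selection keeps features with votes >= T.

# vectorized Welch t test p-values over matrix columns, NA-tolerant
welch_p <- function(x1, x2) {
  n1 <- colSums(!is.na(x1)); n2 <- colSums(!is.na(x2))
  m1 <- colMeans(x1, na.rm = TRUE); m2 <- colMeans(x2, na.rm = TRUE)
  v1 <- colSums(sweep(x1, 2, m1)^2, na.rm = TRUE) / pmax(n1 - 1, 1)
  v2 <- colSums(sweep(x2, 2, m2)^2, na.rm = TRUE) / pmax(n2 - 1, 1)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  p <- 2 * pt(abs(t_stat), df, lower.tail = FALSE)
  p[n1 < 2 | n2 < 2 | se2 == 0] <- NA_real_
  p
}

#' Rank features by repeated-subsample t-test voting
#'
#' @param x subjects x features numeric matrix (or `feature_matrix`).
#' @param labels two-level factor (responder / nonresponder), aligned with
#'   rows of `x`; ignored when `x` is a `feature_matrix`.
#' @param n_iterations number of subsample draws (default 100).
#' @param fraction subsample fraction (default 0.8), drawn without
#'   replacement, stratified by class.
#' @param alpha per-iteration significance criterion for a vote
#'   (default 0.05).
#' @param seed integer seed; votes are deterministic given the seed.
#' @return object of class `vote_table`: data.frame (feature, votes)
#'   plus attributes n_iterations, fraction, alpha, seed. Features that
#'   are entirely missing are dropped with a message.
#' @export
rank_features <- function(x, labels = NULL, n_iterations = 100,
                          fraction = 0.8, alpha = 0.05, seed = 1L) {
  if (inherits(x, "feature_matrix")) {
    labels <- x$label
    x <- x$values
  }
  stopifnot(is.matrix(x), length(labels) == nrow(x))
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) != 2)
    stop("both classes must be present")
  keep <- colSums(!is.na(x)) > 0
  if (any(!keep)) {
    message("dropping ", sum(!keep), " all-missing feature(s)")
    x <- x[, keep, drop = FALSE]
  }
  cls <- split(seq_len(nrow(x)), labels)
  n_take <- lapply(cls, function(i) max(2L, round(fraction * length(i))))
  set.seed(as.integer(seed))
  votes <- rep(0L, ncol(x))
  for (it in seq_len(n_iterations)) {
    i1 <- sample(cls[[1]], n_take[[1]])
    i2 <- sample(cls[[2]], n_take[[2]])
    p <- welch_p(x[i1, , drop = FALSE], x[i2, , drop = FALSE])
    votes <- votes + as.integer(!is.na(p) & p < alpha)
  }
  out <- data.frame(feature = colnames(x) %||% as.character(seq_len(ncol(x))),
                    votes = votes, stringsAsFactors = FALSE)
  structure(out, class = c("vote_table", "data.frame"),
            n_iterations = n_iterations, fraction = fraction,
            alpha = alpha, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select features by vote threshold
#'
#' Keeps features whose vote count is `>= T` (inclusive threshold).
#'
#' @param votes a `vote_table`.
#' @param T vote threshold in `[0, n_iterations]`.
#' @return character vector of selected feature names.
#' @export
select_features <- function(votes, T = 60) {
  n_it <- attr(votes, "n_iterations")
  if (T < 0 || T > n_it)
    stop("configuration error: T must be in [0, ", n_it, "]")
  sel <- votes$feature[votes$votes >= T]
  if (!length(sel))
    stop("no feature reaches vote threshold T = ", T,
         "; lower the threshold")
  sel
}
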