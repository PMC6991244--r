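# Monte Carlo estimate of the outcome-label-noise ceiling on balanced
# accuracy: if the clinician-rated scores defining responder status carry
# measurement noise, even a predictor that always outputs the true label
# scores below 100% against the observed (noisy) labels. The ceiling is
# the expected balanced accuracy of that oracle predictor.

#' Estimate the label-noise accuracy ceiling
#'
#' Per replicate, the supplied baseline/week-8 score pairs are treated as
#' true; independent normal noise with SD `sigma` is added to the measured
#' scores (to both visits by default, or only to week 8), observed labels
#' are derived from the noisy scores by the >= 50% decrease rule, and the
#' oracle that always emits the true (noise-free) label is scored against
#' them. The ceiling is the mean oracle balanced accuracy over replicates.
#'
#' @param baseline,week8 true MADRS scores per subject (baseline > 0).
#' @param sigma measurement noise SD, MADRS points (>= 0).
#' @param n_replicates Monte Carlo replicates (>= 100).
#' @param noise_on `"both"` (default) or `"week8"`.
#' @param seed integer seed.
#' @param ci_level percentile confidence-interval level (default 0.95).
#' @return list: `ceiling` (%), `ci` (length-2 %), `sigma`,
#'   `n_replicates`, `noise_on`.
#' @export
estimate_ceiling <- function(baseline, week8, sigma, n_replicates = 1000,
                             noise_on = c("both", "week8"), seed = 1L,
                             ci_level = 0.95) {
  noise_on <- match.arg(noise_on)
  if (sigma < 0) stop("configuration error: sigma must be >= 0")
  if (n_replicates < 100)
    stop("configuration error: n_replicates must be >= 100")
  stopifnot(length(baseline) == length(week8), all(baseline > 0))
  true_lab <- label_responder(baseline, week8)
  if (nlevels(droplevels(true_lab)) < 2)
    stop("cohort must contain both true responders and nonresponders")
  n <- length(baseline)
  set.seed(as.integer(seed))
  ba <- numeric(n_replicates)
  for (rep_i in seq_len(n_replicates)) {
    b_obs <- baseline + if (noise_on == "both") rnorm(n, 0, sigma) else 0
    w_obs <- week8 + rnorm(n, 0, sigma)
    b_obs <- pmax(b_obs, 1e-6)           # keep the percent change defined
    obs_lab <- label_responder(b_obs, w_obs)
    cc <- confusion_counts(obs_lab, true_lab)  # truth = observed labels
    r <- report_from_counts(cc)
    # degenerate replicate (all observed labels one class): score the
    # defined rate only
    ba[rep_i] <- if (is.na(r$balanced_accuracy)) {
      if (is.na(r$sensitivity)) r$specificity else r$sensitivity
    } else r$balanced_accuracy
  }
  a <- (1 - ci_level) / 2
  list(ceiling = mean(ba),
       ci = unname(quantile(ba, c(a, 1 - a))),
       sigma = sigma, n_replicates = n_replicates, noise_on = noise_on)
}
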