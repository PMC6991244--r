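# Clinical tables, MADRS change and responder labeling.
#
# A subject is a responder when the MADRS score decreased by at least 50%
# between baseline and week 8; the boundary is inclusive. Subjects without
# a week-8 score have no defined label and are excluded from modeling.

#' Percent decrease in MADRS score
#'
#' @param baseline MADRS at baseline (> 0).
#' @param week8 MADRS at week 8.
#' @return `100 * (baseline - week8) / baseline`; negative when the score
#'   worsened. Vectorized.
#' @export
percent_decrease <- function(baseline, week8) {
  if (any(!is.finite(baseline) | !is.finite(week8)))
    stop("undefined-label error: non-finite MADRS score")
  if (any(baseline <= 0))
    stop("undefined-label error: baseline MADRS must be > 0")
  100 * (baseline - week8) / baseline
}

#' Responder / nonresponder label from MADRS scores
#'
#' Responder iff the percent decrease from baseline to week 8 is >= 50
#' (inclusive boundary). Vectorized; `NA` week-8 scores yield `NA` labels.
#'
#' @inheritParams percent_decrease
#' @return factor with levels `nonresponder`, `responder`.
#' @export
label_responder <- function(baseline, week8) {
  out <- rep(NA_character_, length(baseline))
  ok <- is.finite(baseline) & is.finite(week8)
  if (any(is.finite(baseline) & baseline <= 0))
    stop("undefined-label error: baseline MADRS must be > 0")
  out[ok] <- ifelse(percent_decrease(baseline[ok], week8[ok]) >= 50,
                    "responder", "nonresponder")
  factor(out, levels = c("nonresponder", "responder"))
}

#' Read a clinical table from CSV
#'
#' Strict schema: subject_id, site, age, sex, madrs_baseline, madrs_week2,
#' madrs_week8 (extra columns preserved); empty fields become `NA`.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_clinical <- function(path) {
  required <- c("subject_id", "site", "age", "sex",
                "madrs_baseline", "madrs_week2", "madrs_week8")
  x <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("clinical table missing column(s): ", paste(missing, collapse = ", "))
  for (col in grep("^madrs_", names(x), value = TRUE)) {
    bad <- which(!is.na(x[[col]]) & (x[[col]] < 0 | x[[col]] > 60))
    if (length(bad))
      stop("MADRS scores outside [0, 60] in column ", col)
  }
  x
}

#' Cohort summary table
#'
#' Per-site and overall counts, responder counts/percentages (1 decimal),
#' and mean (SD) MADRS per visit and decreases, mirroring a standard
#' baseline-characteristics table. Sites with no subjects are omitted with
#' a warning.
#'
#' @param records clinical data.frame (see [read_clinical()]).
#' @return data.frame, one row per site plus an `All` row.
#' @export
cohort_summary <- function(records) {
  if (!nrow(records)) stop("empty cohort")
  lab <- label_responder(records$madrs_baseline, records$madrs_week8)
  strata <- c(split(seq_len(nrow(records)), records$site),
              list(All = seq_len(nrow(records))))
  empty <- names(strata)[vapply(strata, length, 0L) == 0]
  if (length(empty)) {
    warning("empty site stratum omitted: ", paste(empty, collapse = ", "))
    strata <- strata[vapply(strata, length, 0L) > 0]
  }
  msd <- function(x) sprintf("%.1f (%.1f)", mean(x, na.rm = TRUE),
                             sd(x, na.rm = TRUE))
  rows <- lapply(names(strata), function(s) {
    i <- strata[[s]]
    r <- records[i, ]
    nresp <- sum(lab[i] == "responder", na.rm = TRUE)
    ndef <- sum(!is.na(lab[i]))
    dec <- r$madrs_baseline - r$madrs_week8
    pdec <- percent_decrease(r$madrs_baseline,
                             ifelse(is.na(r$madrs_week8), r$madrs_baseline,
                                    r$madrs_week8))
    pdec[is.na(r$madrs_week8)] <- NA
    data.frame(
      site = s, n = nrow(r),
      responders = nresp,
      responder_pct = round(100 * nresp / ndef, 1),
      madrs_baseline = msd(r$madrs_baseline),
      madrs_week2 = msd(r$madrs_week2),
      madrs_week8 = msd(r$madrs_week8),
      decrease = msd(dec),
      decrease_pct = msd(pdec),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
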