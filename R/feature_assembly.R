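# Assembly of per-subject feature vectors into subjects x features
# matrices, and construction of the four feature sources: baseline,
# week 2, early change (week 2 minus baseline) and combined
# (baseline union early change).

#' Construct a feature matrix from per-subject feature tables
#'
#' @param feature_tables named list (by subject id) of data.frames with
#'   columns class, location, band_or_scale, value — the output of the
#'   per-recording feature extractors.
#' @param clinical clinical data.frame aligned by subject_id (supplies
#'   site and MADRS scores for labels).
#' @param source_tag one of "baseline", "week2", "early_change".
#' @return object of class `feature_matrix`: `values` (subjects x
#'   features), `descriptors` (class, location, band_or_scale, source_tag,
#'   key), `subject_id`, `site`, `label`.
#' @export
feature_matrix <- function(feature_tables, clinical,
                           source_tag = "baseline") {
  stopifnot(length(feature_tables) > 0, !is.null(names(feature_tables)))
  d0 <- feature_tables[[1]][c("class", "location", "band_or_scale")]
  key <- paste(d0$class, d0$location, d0$band_or_scale, source_tag, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate feature descriptor key(s)")
  vals <- t(vapply(feature_tables, function(tb) {
    k <- paste(tb$class, tb$location, tb$band_or_scale, source_tag, sep = "|")
    if (!identical(k, key)) stop("feature tables are not aligned")
    tb$value
  }, numeric(length(key))))
  rownames(vals) <- names(feature_tables)
  colnames(vals) <- key
  ids <- names(feature_tables)
  ci <- match(ids, clinical$subject_id)
  if (anyNA(ci)) stop("subject(s) missing from clinical table: ",
                      paste(ids[is.na(ci)], collapse = ", "))
  lab <- label_responder(clinical$madrs_baseline[ci],
                         clinical$madrs_week8[ci])
  structure(list(
    values = vals,
    descriptors = data.frame(d0, source_tag = source_tag, key = key,
                             stringsAsFactors = FALSE),
    subject_id = ids, site = clinical$site[ci], label = lab),
    class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d subjects x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$descriptors$source_tag), collapse = "+")))
  invisible(x)
}

#' Build a feature source from baseline and week-2 feature matrices
#'
#' Sources: `baseline` (all subjects); `week2` (week-2 subjects);
#' `early_change` = week-2 value minus baseline value per feature, on the
#' week-2 subject subset; `combined` = column-wise union of baseline and
#' early-change features on the week-2 subset (source tags keep duplicate
#' descriptors distinct).
#'
#' @param fm_baseline `feature_matrix` with source_tag "baseline".
#' @param fm_week2 `feature_matrix` with source_tag "week2" (same feature
#'   layout), or NULL for source = "baseline".
#' @param source one of "baseline", "week2", "early_change", "combined".
#' @return a `feature_matrix`.
#' @export
build_source <- function(fm_baseline, fm_week2 = NULL,
                         source = c("baseline", "week2", "early_change",
                                    "combined")) {
  source <- match.arg(source)
  if (source == "baseline") return(fm_baseline)
  stopifnot(inherits(fm_week2, "feature_matrix"))
  if (source == "week2") return(fm_week2)
  ids <- intersect(fm_week2$subject_id, fm_baseline$subject_id)
  if (!length(ids)) stop("no subjects present at both timepoints")
  bi <- match(ids, fm_baseline$subject_id)
  wi <- match(ids, fm_week2$subject_id)
  db <- fm_baseline$descriptors
  dw <- fm_week2$descriptors
  kb <- paste(db$class, db$location, db$band_or_scale, sep = "|")
  kw <- paste(dw$class, dw$location, dw$band_or_scale, sep = "|")
  if (!identical(kb, kw))
    stop("baseline and week-2 matrices have different feature layouts")
  ec_vals <- fm_week2$values[wi, , drop = FALSE] -
    fm_baseline$values[bi, , drop = FALSE]
  ec_desc <- data.frame(db[c("class", "location", "band_or_scale")],
                        source_tag = "early_change",
                        stringsAsFactors = FALSE)
  ec_desc$key <- paste(ec_desc$class, ec_desc$location,
                       ec_desc$band_or_scale, "early_change", sep = "|")
  colnames(ec_vals) <- ec_desc$key
  rownames(ec_vals) <- ids
  ec <- structure(list(values = ec_vals, descriptors = ec_desc,
                       subject_id = ids, site = fm_week2$site[wi],
                       label = fm_week2$label[wi]),
                  class = "feature_matrix")
  if (source == "early_change") return(ec)
  # combined: baseline features restricted to the week-2 subset + early change
  comb_vals <- cbind(fm_baseline$values[bi, , drop = FALSE], ec$values)
  comb_desc <- rbind(fm_baseline$descriptors, ec$descriptors)
  if (anyDuplicated(comb_desc$key)) stop("duplicate keys in combined source")
  structure(list(values = comb_vals, descriptors = comb_desc,
                 subject_id = ids, site = fm_week2$site[wi],
                 label = fm_week2$label[wi]),
            class = "feature_matrix")
}

#' Extract all four feature classes for a list of preprocessed recordings
#'
#' Runs the spectral, multiscale-entropy, source-space and microstate
#' extractors per subject and assembles a `feature_matrix`. The microstate
#' model is fitted at group level (across all supplied recordings) and the
#' eLORETA operator is computed once from the leadfield.
#'
#' @param prep_list named list (by subject id) of [preprocess_recording()]
#'   outputs (each with `narrow` and `wide` elements).
#' @param clinical clinical data.frame.
#' @param source_tag "baseline" or "week2".
#' @param leadfield optional `leadfield` for source features (skipped when
#'   NULL).
#' @param band_grid band definitions.
#' @param mse_cfg an [mse_config()].
#' @param microstate_k classes for microstate fitting (0 skips microstates).
#' @param seed integer seed for microstate fitting / peak pooling.
#' @return a `feature_matrix`.
#' @export
extract_cohort_features <- function(prep_list, clinical,
                                    source_tag = "baseline",
                                    leadfield = NULL,
                                    band_grid = default_band_grid(),
                                    mse_cfg = mse_config(),
                                    microstate_k = 4, seed = 1L) {
  stopifnot(length(prep_list) > 0)
  ms_model <- NULL
  if (microstate_k > 0) {
    peaks <- pool_gfp_peaks(lapply(prep_list, `[[`, "narrow"), seed = seed)
    ms_model <- fit_microstates(peaks, k = microstate_k, seed = seed)
  }
  operator <- if (!is.null(leadfield))
    eloreta_inverse(leadfield) else NULL
  tables <- lapply(prep_list, function(pp) {
    tb <- rbind(spectral_features(pp$narrow, band_grid),
                mse_features(pp$wide, mse_cfg))
    if (!is.null(operator)) {
      sb <- source_band_power(pp$narrow, operator, leadfield$roi, band_grid)
      sb$value <- log10(pmax(sb$value, .Machine$double.xmin))
      tb <- rbind(tb, sb)
    }
    if (!is.null(ms_model))
      tb <- rbind(tb, microstate_features(pp$narrow, ms_model))
    tb
  })
  feature_matrix(tables, clinical, source_tag)
}

#' Write a feature matrix (values + descriptor side-table) to CSV
#'
#' @param fm a `feature_matrix`.
#' @param values_path,descriptors_path output CSV paths.
#' @return invisibly, `values_path`.
#' @export
write_feature_matrix <- function(fm, values_path, descriptors_path) {
  df <- data.frame(subject_id = fm$subject_id, site = fm$site,
                   label = as.character(fm$label),
                   fm$values, check.names = FALSE)
  write.csv(df, values_path, row.names = FALSE)
  write.csv(fm$descriptors, descriptors_path, row.names = FALSE)
  invisible(values_path)
}
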