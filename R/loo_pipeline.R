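# Leave-one-out evaluation with nested selection.
#
# For each held-out subject, every fitted artifact -- group Z maps, ROI,
# PC basis, model map -- is computed from the remaining n - 1 subjects
# only; the held-out subject's features enter only at projection and
# prediction time. This nesting is the central correctness property of the
# whole method: the held-out psychometric scores can influence nothing in
# the fold that predicts them.

#' Run the leave-one-out pipeline
#'
#' @param contrast_sets Named list of per-subject [contrast_set()] objects.
#' @param records Cohort data frame aligned with `contrast_sets`.
#' @param roi_cfg A [roi_config()].
#' @param clf_cfg A [classifier_config()].
#' @param n_components Principal components per fold (default 2).
#' @param feature_source `"effect"` or `"z"`, see [assemble_features()].
#' @return A `loo_result`: list of per-fold results, each with
#'   `held_out_id`, `roi_size`, `predicted` (bdi_pred, aai_pred),
#'   `depressed_predicted`, `insecure_predicted`, and the fold's fitted
#'   `basis`, `map` and `mask`. Deterministic given its inputs.
#' @export
run_loo <- function(contrast_sets, records, roi_cfg = roi_config(),
                    clf_cfg = classifier_config(), n_components = 2L,
                    feature_source = "effect") {
  n <- nrow(records)
  if (n < 5L) stopf("leave-one-out needs at least 5 subjects, got %d", n)
  if (length(contrast_sets) != n)
    stopf("%d contrast sets for %d subjects", length(contrast_sets), n)
  folds <- lapply(seq_len(n), function(i) {
    id <- records$subject_id[i]
    res <- tryCatch({
      sample_idx <- setdiff(seq_len(n), i)
      zm <- group_zmaps(contrast_sets[sample_idx],
                        records[sample_idx, , drop = FALSE])
      mask <- withCallingHandlers(
        select_roi(zm, roi_cfg),
        warning = function(w) invokeRestart("muffleWarning"))
      Fs <- assemble_features(contrast_sets[sample_idx], mask,
                              source = feature_source)
      Ft <- assemble_features(contrast_sets[[i]], mask,
                              source = feature_source)
      basis <- extract_pcs(Fs, k = n_components)
      W <- t(vapply(seq_len(nrow(Fs)),
                    function(r) subject_weights(Fs[r, ], basis),
                    numeric(n_components + 1L)))
      Y <- cbind(bdi = as.numeric(records$bdi[sample_idx]),
                 aai = as.numeric(records$aai[sample_idx]))
      map <- fit_model_map(W, Y)
      wrow <- subject_weights(Ft[1L, ], basis)
      pred <- predict_scores(wrow, map)
      if (any(!is.finite(pred)))
        stopf("prediction is not finite")
      list(held_out_id = id, roi_size = length(mask$indices),
           predicted = pred,
           depressed_predicted = classify_depression(pred, clf_cfg),
           insecure_predicted = classify_attachment(pred, clf_cfg),
           basis = basis, map = map, mask = mask)
    }, error = function(e) {
      stopf("fold for held-out subject '%s' failed: %s", id,
            conditionMessage(e))
    })
    res
  })
  structure(folds, class = "loo_result")
}

#' Confusion-matrix diagnostics
#'
#' `sensitivity = 100 TP / (TP + FN)`, `specificity = 100 TN / (TN + FP)`,
#' `agreement = 100 (TP + TN) / n`. A zero denominator yields `NA` with a
#' warning, never a silent 0/0.
#'
#' @param predicted_labels,true_labels Logical vectors (`TRUE` = positive)
#'   of equal length, or two-level factors/characters where the positive
#'   level is given by `positive`.
#' @param positive Label value counted as positive when the inputs are not
#'   logical.
#' @return List with `sensitivity`, `specificity`, `agreement` (percent)
#'   and `confusion` (named counts TP, FP, TN, FN).
#' @export
confusion_metrics <- function(predicted_labels, true_labels,
                              positive = TRUE) {
  if (length(predicted_labels) != length(true_labels))
    stopf("label vectors differ in length")
  as_bin <- function(x) {
    if (is.logical(x)) return(x)
    u <- unique(as.character(x))
    if (length(setdiff(u, c(as.character(positive), u))) || length(u) > 2L)
      stopf("labels must be binary")
    as.character(x) == as.character(positive)
  }
  p <- as_bin(predicted_labels); y <- as_bin(true_labels)
  if (any(is.na(p)) || any(is.na(y))) stopf("labels must not be NA")
  tp <- sum(p & y); fp <- sum(p & !y)
  tn <- sum(!p & !y); fn <- sum(!p & y)
  rate <- function(num, den, what) {
    if (den == 0L) {
      warning(sprintf("%s undefined: no %s cases", what,
                      if (what == "sensitivity") "positive" else "negative"),
              call. = FALSE)
      return(NA_real_)
    }
    100 * num / den
  }
  list(sensitivity = rate(tp, tp + fn, "sensitivity"),
       specificity = rate(tn, tn + fp, "specificity"),
       agreement = 100 * (tp + tn) / length(y),
       confusion = c(TP = tp, FP = fp, TN = tn, FN = fn))
}

#' Pearson correlation of predicted and measured scores
#'
#' @param predicted,measured Equal-length numeric vectors (>= 3 values).
#' @return Pearson product-moment r.
#' @export
score_correlation <- function(predicted, measured) {
  if (length(predicted) != length(measured))
    stopf("score vectors differ in length")
  if (length(predicted) < 3L) stopf("need at least 3 score pairs")
  if (sd(predicted) == 0 || sd(measured) == 0)
    stopf("correlation undefined: a score vector has zero variance")
  cor(predicted, measured)
}

#' Evaluate leave-one-out predictions
#'
#' Depression truth is the cohort `group` label; measured insecure
#' attachment is `aai < aai_cut`. The AAI agreement additionally carries an
#' exact binomial test against chance (p = 0.5), since prediction of
#' attachment security is expected to be the weaker signal.
#'
#' @param folds A [run_loo()] result.
#' @param records The cohort data frame the folds were run on.
#' @param clf_cfg The [classifier_config()] used.
#' @return An `evaluation_report`: depression `sensitivity`, `specificity`,
#'   `agreement` and `confusion`; `pearson_r_bdi`, `pearson_r_aai`;
#'   `aai_agreement` and `aai_p_value`; and a `per_subject` data frame.
#' @export
evaluate_loo <- function(folds, records, clf_cfg = classifier_config()) {
  stopifnot(inherits(folds, "loo_result"))
  ids <- vapply(folds, `[[`, character(1), "held_out_id")
  if (!identical(ids, records$subject_id))
    stopf("fold order does not match the cohort records")
  per_subject <- data.frame(
    subject_id = ids,
    bdi_measured = records$bdi,
    bdi_predicted = vapply(folds, function(f) f$predicted[["bdi_pred"]],
                           numeric(1)),
    depressed_measured = records$group == "depressed",
    depressed_predicted = vapply(folds, `[[`, character(1),
                                 "depressed_predicted") == "depressed",
    aai_measured = records$aai,
    aai_predicted = vapply(folds, function(f) f$predicted[["aai_pred"]],
                           numeric(1)),
    insecure_measured = records$aai < clf_cfg$aai_cut,
    insecure_predicted = vapply(folds, `[[`, character(1),
                                "insecure_predicted") == "insecure",
    roi_size = vapply(folds, `[[`, integer(1), "roi_size"),
    stringsAsFactors = FALSE)
  dep <- confusion_metrics(per_subject$depressed_predicted,
                           per_subject$depressed_measured)
  aai_ok <- per_subject$insecure_predicted == per_subject$insecure_measured
  aai_test <- binom.test(sum(aai_ok), length(aai_ok), p = 0.5)
  structure(list(
    sensitivity = dep$sensitivity, specificity = dep$specificity,
    agreement = dep$agreement, confusion = dep$confusion,
    pearson_r_bdi = score_correlation(per_subject$bdi_predicted,
                                      per_subject$bdi_measured),
    pearson_r_aai = score_correlation(per_subject$aai_predicted,
                                      per_subject$aai_measured),
    aai_agreement = 100 * mean(aai_ok),
    aai_p_value = aai_test$p.value,
    per_subject = per_subject), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  n <- nrow(x$per_subject)
  cf <- x$confusion
  cat("Leave-one-out evaluation\n")
  cat(sprintf("  depression: agreement %.1f%% (%d/%d), sensitivity %.1f%% (%d/%d), specificity %.1f%% (%d/%d)\n",
              x$agreement, cf[["TP"]] + cf[["TN"]], n,
              x$sensitivity, cf[["TP"]], cf[["TP"]] + cf[["FN"]],
              x$specificity, cf[["TN"]], cf[["TN"]] + cf[["FP"]]))
  cat(sprintf("  predicted vs measured BDI-II: r = %.2f\n", x$pearson_r_bdi))
  cat(sprintf("  predicted vs measured AAI:    r = %.2f\n", x$pearson_r_aai))
  cat(sprintf("  attachment: agreement %.1f%% (binomial p = %.2f vs chance; interpret cautiously)\n",
              x$aai_agreement, x$aai_p_value))
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' Raw fractions are stored alongside the rounded percentages so printed
#' values are never ambiguous.
#'
#' @param report An [evaluate_loo()] report.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  cf <- report$confusion
  n <- nrow(report$per_subject)
  obj <- list(
    sensitivity_pct = report$sensitivity,
    specificity_pct = report$specificity,
    agreement_pct = report$agreement,
    sensitivity_fraction = sprintf("%d/%d", cf[["TP"]],
                                   cf[["TP"]] + cf[["FN"]]),
    specificity_fraction = sprintf("%d/%d", cf[["TN"]],
                                   cf[["TN"]] + cf[["FP"]]),
    agreement_fraction = sprintf("%d/%d", cf[["TP"]] + cf[["TN"]], n),
    confusion = as.list(cf),
    pearson_r_bdi = report$pearson_r_bdi,
    pearson_r_aai = report$pearson_r_aai,
    aai_agreement_pct = report$aai_agreement,
    aai_p_value = report$aai_p_value,
    per_subject = report$per_subject)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Full-cohort ROI for inspection
#'
#' The ROI recomputed on all subjects (the fold masks are what predictions
#' use; this one is the reporting/inspection mask).
#'
#' @param contrast_sets Per-subject [contrast_set()] list.
#' @param records Cohort data frame.
#' @param roi_cfg A [roi_config()].
#' @return A [roi_mask()].
#' @export
cohort_roi <- function(contrast_sets, records, roi_cfg = roi_config()) {
  select_roi(group_zmaps(contrast_sets, records), roi_cfg)
}

#' Predictions data frame in the CSV layout of [write_predictions()]
#'
#' @param report An [evaluate_loo()] report.
#' @return Data frame ready for [write_predictions()].
#' @export
report_predictions <- function(report) {
  ps <- report$per_subject
  data.frame(subject_id = ps$subject_id,
             bdi_measured = ps$bdi_measured,
             bdi_predicted = ps$bdi_predicted,
             depressed_measured = ps$depressed_measured,
             depressed_predicted = ps$depressed_predicted,
             aai_measured = ps$aai_measured,
             aai_predicted = ps$aai_predicted,
             insecure_predicted = ps$insecure_predicted,
             stringsAsFactors = FALSE)
}
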