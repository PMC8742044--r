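# Confusion-matrix metrics, ROC/AUC and the model-comparison harness.
# Disease is the positive class; health is the negative class.

#' Confusion counts
#'
#' @param true_labels,predicted_labels equal-length 0/1 vectors (1 =
#'   diseased/positive).
#' @return list of class `confusion_counts` with integers `TP`, `FP`, `TN`,
#'   `FN`.
#' @export
confusion <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors differ in length")
  if (!all(true_labels %in% c(0, 1)) || !all(predicted_labels %in% c(0, 1)))
    stop("labels must be binary 0/1")
  structure(list(TP = sum(true_labels == 1 & predicted_labels == 1),
                 FP = sum(true_labels == 0 & predicted_labels == 1),
                 TN = sum(true_labels == 0 & predicted_labels == 0),
                 FN = sum(true_labels == 1 & predicted_labels == 0)),
            class = "confusion_counts")
}

#' Sensitivity, specificity and accuracy
#'
#' Evaluates SE = TP/(TP+FN), SP = TN/(TN+FP) and
#' ACC = (TP+TN)/(TP+TN+FP+FN). A zero denominator yields `NA` for that
#' metric with a warning rather than a silent 0.
#'
#' @param counts a [confusion()] result.
#' @return named numeric vector `c(se, sp, acc)`.
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tot <- counts$TP + counts$TN + counts$FP + counts$FN
  if (tot == 0) stop("no evaluated samples: all counts are zero")
  se <- if (counts$TP + counts$FN > 0) counts$TP / (counts$TP + counts$FN)
        else { warning("SE undefined: no positive samples"); NA_real_ }
  sp <- if (counts$TN + counts$FP > 0) counts$TN / (counts$TN + counts$FP)
        else { warning("SP undefined: no negative samples"); NA_real_ }
  c(se = se, sp = sp, acc = (counts$TP + counts$TN) / tot)
}

#' ROC curve and AUC
#'
#' Sweeps every distinct score as a threshold (ties grouped at one
#' threshold), yielding ROC points from (0,0) to (1,1); the AUC is the
#' trapezoidal integral, which under this construction equals the rank
#' statistic P(score_pos > score_neg) + 0.5 P(equal) (midrank tie
#' convention).
#'
#' @param scores real-valued scores, larger = more disease-like.
#' @param true_labels 0/1 labels; both categories must be present.
#' @return list with `roc` (`data.frame` of `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, true_labels) {
  if (length(scores) != length(true_labels)) stop("length mismatch")
  P <- sum(true_labels == 1); N <- sum(true_labels == 0)
  if (P == 0 || N == 0)
    stop("ROC undefined: only one category present in true_labels")
  ths <- sort(unique(scores), decreasing = TRUE)
  tpr <- numeric(length(ths) + 1L)
  fpr <- numeric(length(ths) + 1L)
  for (i in seq_along(ths)) {
    pred <- scores >= ths[i]
    tpr[i + 1L] <- sum(pred & true_labels == 1) / P
    fpr[i + 1L] <- sum(pred & true_labels == 0) / N
  }
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(threshold = c(Inf, ths), fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Full metrics report for scored predictions
#'
#' Hard calls at `threshold` (default 0.5 on the softmax probability) give
#' the confusion counts and SE/SP/ACC; the ROC/AUC use the raw scores.
#'
#' @param scores P(diseased) per image.
#' @param true_labels 0/1 labels.
#' @param threshold hard-call threshold.
#' @return object of class `metrics_report`: `counts`, `se`, `sp`, `acc`,
#'   `roc`, `auc`, `threshold`.
#' @export
metrics_report <- function(scores, true_labels, threshold = 0.5) {
  counts <- confusion(true_labels, as.integer(scores >= threshold))
  m <- suppressWarnings(classification_metrics(counts))
  r <- roc_auc(scores, true_labels)
  structure(list(counts = counts, se = unname(m["se"]), sp = unname(m["sp"]),
                 acc = unname(m["acc"]),
                 roc = r$roc, auc = r$auc, threshold = threshold),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("SE %.2f%%  SP %.2f%%  ACC %.2f%%  AUC %.3f (threshold %.2f)\n",
              100 * x$se, 100 * x$sp, 100 * x$acc, x$auc, x$threshold))
  invisible(x)
}

#' Compare cross-validated models
#'
#' One row per model with the mean SE/SP/ACC/AUC over folds, mirroring the
#' usual "SE (%) SP (%) AUC" comparison layout. Results evaluated on
#' different fold plans are refused.
#'
#' @param cv_results named list of [run_crossvalidation()] results.
#' @return `data.frame` with columns `model`, `se_pct`, `sp_pct`, `acc_pct`,
#'   `auc`.
#' @export
compare_models <- function(cv_results) {
  stopifnot(length(cv_results) >= 1)
  fps <- vapply(cv_results, function(r) r$plan_fingerprint, character(1))
  if (length(unique(fps)) != 1)
    stop("fold-plan mismatch: results come from different split plans")
  rows <- lapply(names(cv_results), function(nm) {
    m <- cv_results[[nm]]$mean
    data.frame(model = nm, se_pct = 100 * m["se"], sp_pct = 100 * m["sp"],
               acc_pct = 100 * m["acc"], auc = m["auc"],
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Serialize a metrics report as delimited text
#'
#' @param report a `metrics_report`.
#' @param path output file.
#' @export
write_metrics_report <- function(report, path) {
  df <- data.frame(metric = c("TP", "FP", "TN", "FN", "SE", "SP", "ACC", "AUC"),
                   value = c(report$counts$TP, report$counts$FP,
                             report$counts$TN, report$counts$FN,
                             report$se, report$sp, report$acc, report$auc))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
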