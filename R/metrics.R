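#' Confusion counts for binary predictions
#'
#' @param pred,truth Equal-length vectors of 0/1 labels.
#' @return A list of class `"patchboost_confusion"` with integer fields
#'   `TP`, `TN`, `FP`, `FN` (their sum is the number of samples).
#' @export
confusion <- function(pred, truth) {
  if (length(pred) == 0L) stop("empty input")
  if (length(pred) != length(truth)) {
    stop("pred and truth lengths differ (", length(pred), " vs ",
         length(truth), ")")
  }
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1))) {
    stop("pred and truth must be binary (0/1)")
  }
  structure(list(TP = sum(pred == 1 & truth == 1),
                 TN = sum(pred == 0 & truth == 0),
                 FP = sum(pred == 1 & truth == 0),
                 FN = sum(pred == 0 & truth == 1)),
            class = "patchboost_confusion")
}

#' Accuracy, sensitivity, specificity and F-measure from confusion counts
#'
#' Standard binary-classification indicators:
#' `ACC = (TP + TN) / (TP + FP + TN + FN)`, `SEN = TP / (TP + FN)`,
#' `SPE = TN / (TN + FP)`, `F = 2 TP / (2 TP + FN + FP)`. A metric whose
#' denominator is zero is undefined and returned as `NA` (a flagged
#' missing value, never silently 0, so that across-seed aggregation is not
#' corrupted).
#'
#' @param c A [confusion()] object.
#' @return A number in `[0, 1]`, or `NA` when undefined.
#' @export
accuracy <- function(c) safe_ratio(c$TP + c$TN, c$TP + c$FP + c$TN + c$FN)

#' @rdname accuracy
#' @export
sensitivity <- function(c) safe_ratio(c$TP, c$TP + c$FN)

#' @rdname accuracy
#' @export
specificity <- function(c) safe_ratio(c$TN, c$TN + c$FP)

#' @rdname accuracy
#' @export
f_measure <- function(c) safe_ratio(2 * c$TP, 2 * c$TP + c$FN + c$FP)

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Area under the ROC curve
#'
#' Trapezoidal integration of the ROC curve with proper tie handling; the
#' result equals the Mann-Whitney probability that a uniformly drawn
#' positive outscores a uniformly drawn negative, with ties counted one
#' half. Both classes must be present.
#'
#' @param scores Numeric scores for the positive class.
#' @param labels 0/1 labels of the same length.
#' @return AUC in `[0, 1]` (a worse-than-chance scorer can fall below 0.5).
#' @export
auc_score <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary (0/1)")
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  if (P == 0L || N == 0L) {
    stop("AUC requires both classes present (", P, " positives, ", N,
         " negatives)")
  }
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  s <- scores[o]
  grp <- cumsum(!duplicated(s))
  tp <- as.numeric(tapply(y, grp, sum))
  fp <- as.numeric(tapply(1 - y, grp, sum))
  tpr <- c(0, cumsum(tp) / P)
  fpr <- c(0, cumsum(fp) / N)
  sum(diff(fpr) * (tpr[-length(tpr)] + tpr[-1L]) / 2)
}

#' Full metrics report from scores and labels
#'
#' Computes the five evaluation indicators (ACC, AUC, SEN, SPE, F) from
#' positive-class scores and true labels. Hard labels are obtained by
#' arg-max over the two classes, i.e. positive iff the positive-class
#' score exceeds 0.5 (a tie at exactly 0.5 resolves to the negative
#' class). With a single-class label vector the AUC is undefined and
#' reported as a flagged `NA`; the threshold metrics are still computed.
#'
#' @param scores Positive-class scores in `[0, 1]` (e.g. softmax
#'   probabilities).
#' @param labels 0/1 labels.
#' @param threshold Decision threshold (default 0.5).
#' @return A list of class `"patchboost_metrics"` with fields `ACC`,
#'   `AUC`, `SEN`, `SPE`, `F`, `n`, `counts`, and `flagged` (names of
#'   undefined metrics).
#' @export
metrics_report <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores > threshold)
  cc <- confusion(pred, labels)
  auc <- tryCatch(auc_score(scores, labels), error = function(e) NA_real_)
  rep <- list(ACC = accuracy(cc), AUC = auc, SEN = sensitivity(cc),
              SPE = specificity(cc), F = f_measure(cc),
              n = length(labels),
              counts = c(TP = cc$TP, TN = cc$TN, FP = cc$FP, FN = cc$FN))
  rep$flagged <- names(which(vapply(rep[c("ACC", "AUC", "SEN", "SPE", "F")],
                                    is.na, logical(1))))
  structure(rep, class = "patchboost_metrics")
}

#' @export
print.patchboost_metrics <- function(x, ...) {
  cat(metrics_csv_header(), "\n", metrics_csv_row(x), "\n", sep = "")
  if (length(x$flagged)) {
    cat("flagged undefined: ", paste(x$flagged, collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Serialize a metrics report
#'
#' `metrics_to_json()` round-trips the report losslessly through JSON;
#' `metrics_csv_row()` formats one CSV row in the conventional results
#' column order (ACC, AUC, SEN, SPE, F) as percentages with two decimals.
#'
#' @param x A `"patchboost_metrics"` report.
#' @return A JSON string, respectively a CSV row string.
#' @export
metrics_to_json <- function(x) {
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA, null = "null",
                   na = "null")
}

#' @rdname metrics_to_json
#' @param json A string produced by `metrics_to_json()`.
#' @export
metrics_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  for (f in c("ACC", "AUC", "SEN", "SPE", "F")) {
    if (is.null(x[[f]])) x[[f]] <- NA_real_
  }
  x$counts <- unlist(x$counts)
  names(x$counts) <- c("TP", "TN", "FP", "FN")
  x$flagged <- as.character(unlist(x$flagged))
  structure(x, class = "patchboost_metrics")
}

metrics_csv_header <- function() "ACC,AUC,SEN,SPE,F"

#' @rdname metrics_to_json
#' @export
metrics_csv_row <- function(x) {
  paste(vapply(c("ACC", "AUC", "SEN", "SPE", "F"), function(f) {
    if (is.na(x[[f]])) "NA" else sprintf("%.2f", 100 * x[[f]])
  }, character(1)), collapse = ",")
}

#' Aggregate metric reports across seeds
#'
#' @param reports A list of `"patchboost_metrics"` reports (e.g. one per
#'   training seed).
#' @return A data.frame with one row per metric: `mean` and, when at least
#'   two runs are supplied, the across-seed `sd`.
#' @export
aggregate_metrics <- function(reports) {
  fields <- c("ACC", "AUC", "SEN", "SPE", "F")
  vals <- vapply(reports, function(r) unlist(r[fields]), numeric(5))
  out <- data.frame(metric = fields,
                    mean = apply(vals, 1L, mean, na.rm = TRUE))
  if (length(reports) >= 2L) out$sd <- apply(vals, 1L, stats::sd, na.rm = TRUE)
  out
}
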