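#' Cross-tabulate binary calls against labels
#'
#' @param calls,labels equal-length binary vectors (0/1).
#' @return a \linkS4class{ConfusionMatrix}.
#' @export
confusionCounts <- function(calls, labels) {
  if (length(calls) != length(labels)) stop("calls and labels differ in length")
  if (length(calls) < 1L) stop("at least one observation required")
  calls <- as.integer(calls); labels <- as.integer(labels)
  stopifnot(all(calls %in% 0:1), all(labels %in% 0:1))
  new("ConfusionMatrix",
      TP = sum(calls == 1L & labels == 1L),
      FP = sum(calls == 1L & labels == 0L),
      TN = sum(calls == 0L & labels == 0L),
      FN = sum(calls == 0L & labels == 1L))
}

.safeRatio <- function(num, den) if (den > 0) num / den else NA_real_

#' Classification metrics from confusion counts
#'
#' accuracy = (TP+TN)/total; recall = sensitivity = TP/(TP+FN);
#' specificity = TN/(TN+FP). A zero denominator yields \code{NA} (flagged
#' missing value), never an error.
#'
#' @param cm a \linkS4class{ConfusionMatrix}.
#' @return scalar in [0, 1], or \code{NA} when undefined.
#' @export
accuracy <- function(cm) {
  .safeRatio(cm@TP + cm@TN, cm@TP + cm@TN + cm@FP + cm@FN)
}

#' @rdname accuracy
#' @export
recall <- function(cm) .safeRatio(cm@TP, cm@TP + cm@FN)

#' @rdname accuracy
#' @export
sensitivity <- function(cm) recall(cm)

#' @rdname accuracy
#' @export
specificity <- function(cm) .safeRatio(cm@TN, cm@TN + cm@FP)

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix: TP=%d FP=%d TN=%d FN=%d (acc %.3f)\n",
              object@TP, object@FP, object@TN, object@FN, accuracy(object)))
})

#' Empirical ROC curve and AUC
#'
#' Sweeps the distinct scores as thresholds (strictly decreasing, call
#' positive when score >= threshold) and integrates the curve by the
#' trapezoidal rule, which equals the pair-counting probability
#' P(score+ > score-) + 0.5 P(tie). The value is not clamped: a
#' worse-than-chance ranker legitimately scores below 0.5.
#'
#' @param scores numeric vector of predicted scores.
#' @param labels binary vector of true classes; both classes must occur.
#' @return list with \code{auc} and \code{roc}, a data.frame of
#'   (threshold, fpr, tpr) from (0,0) to (1,1).
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  nP <- sum(labels == 1L); nN <- sum(labels == 0L)
  if (nP == 0L || nN == 0L) stop("both classes must be present to build a ROC")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / nP, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / nN, numeric(1))
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  if (roc$fpr[nrow(roc)] < 1 || roc$tpr[nrow(roc)] < 1)
    roc <- rbind(roc, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  list(auc = auc, roc = roc)
}

#' Serialize a metrics report
#'
#' @param report named list of metrics.
#' @param path JSON output path.
#' @export
writeMetricsReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
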