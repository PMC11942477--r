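#' Confusion counts between two pair matrices
#'
#' Compares a predicted and a true base-pair contact matrix over the strict
#' upper triangle only, so each unordered pair is counted exactly once.
#'
#' @param pred,truth Binary symmetric L x L matrices (values coerced with
#'   `> 0.5` so probability matrices can be passed directly).
#' @return List of class `"confusion_counts"` with `TP`, `FP`, `FN`, `TN`.
#' @export
pair_confusion <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth)))
    stop("pred and truth must have identical dimensions")
  up <- upper.tri(pred)
  p <- pred[up] > 0.5
  t <- truth[up] > 0.5
  confusion_counts(TP = sum(p & t), FP = sum(p & !t),
                   FN = sum(!p & t), TN = sum(!p & !t))
}

#' Construct confusion counts
#'
#' @param TP,FP,FN True/false positive and false negative counts.
#' @param TN True negatives; may be `NA` for pair-level structure scoring
#'   where negatives are implicit.
#' @return List of class `"confusion_counts"`.
#' @export
confusion_counts <- function(TP, FP, FN, TN = NA) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0, is.na(TN) || TN >= 0)
  structure(list(TP = as.numeric(TP), FP = as.numeric(FP),
                 FN = as.numeric(FN), TN = as.numeric(TN)),
            class = "confusion_counts")
}

#' Positive predictive value, sensitivity and F1
#'
#' `PPV = TP / (TP + FP)`, `Sen = TP / (TP + FN)` and their harmonic mean
#' `F1 = 2 PPV Sen / (PPV + Sen)`.  Any zero denominator yields 0.
#'
#' @param c A [confusion_counts()] object.
#' @return Named numeric vector `c(PPV, SEN, F1)`.
#' @export
ppv_sen_f1 <- function(c) {
  safe_div <- function(a, b) if (b > 0) a / b else 0
  ppv <- safe_div(c$TP, c$TP + c$FP)
  sen <- safe_div(c$TP, c$TP + c$FN)
  f1 <- safe_div(2 * ppv * sen, ppv + sen)
  c(PPV = ppv, SEN = sen, F1 = f1)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the
#' zero-denominator convention MCC = 0.  Requires a defined TN.
#'
#' @param c A [confusion_counts()] object.
#' @return Numeric in `[-1, 1]`.
#' @export
mcc <- function(c) {
  if (is.na(c$TN)) stop("MCC requires a defined TN count")
  den <- sqrt((c$TP + c$FP) * (c$TP + c$FN) * (c$TN + c$FP) * (c$TN + c$FN))
  if (den == 0) return(0)
  (c$TP * c$TN - c$FP * c$FN) / den
}

#' Accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param c A [confusion_counts()] object.
#' @return Numeric in `[0, 1]`.
#' @export
acc <- function(c) {
  if (is.na(c$TN)) stop("ACC requires a defined TN count")
  tot <- c$TP + c$TN + c$FP + c$FN
  if (tot == 0) stop("empty confusion counts")
  (c$TP + c$TN) / tot
}

#' Area under the ROC curve
#'
#' Computed from the rank statistic (Mann-Whitney form) with mid-rank tie
#' handling, so all-equal scores give exactly 0.5.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1 or logical).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUROC needs at least one positive and one negative label")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step integration of the precision-recall curve with tied scores grouped
#' at a single threshold; under all-equal scores the area equals the
#' positive prevalence.
#'
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == 1L)
  if (npos == 0L) stop("AUPRC needs at least one positive label")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1L - y)
  last <- !duplicated(grp, fromLast = TRUE)  # end of each tie group
  tp <- tp[last]; fp <- fp[last]
  rec <- tp / npos
  prec <- tp / (tp + fp)
  sum(diff(c(0, rec)) * prec)
}

#' Full metric report
#'
#' Evaluates PPV/SEN/F1 (and MCC/ACC when TN is defined) from confusion
#' counts, plus AUROC/AUPRC when scores and labels are supplied.
#'
#' @param c A [confusion_counts()] object, or `NULL`.
#' @param scores,labels Optional score/label vectors for the ranking metrics.
#' @return Named numeric vector of metrics.
#' @export
metric_report <- function(c = NULL, scores = NULL, labels = NULL) {
  out <- numeric(0)
  if (!is.null(c)) {
    out <- ppv_sen_f1(c)
    if (!is.na(c$TN)) out <- c(out, MCC = mcc(c), ACC = acc(c))
  }
  if (!is.null(scores)) {
    out <- c(out, AUROC = auroc(scores, labels), AUPRC = auprc(scores, labels))
  }
  out
}

#' Write a metric report as TSV and JSON
#'
#' @param metrics Named numeric vector.
#' @param path Output path without extension, or ending in `.tsv`/`.json`
#'   to write a single format.
#' @export
write_metric_report <- function(metrics, path) {
  df <- data.frame(metric = names(metrics), value = unname(metrics))
  if (grepl("\\.tsv$", path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.list(metrics), path, auto_unbox = TRUE, digits = NA)
  } else {
    write.table(df, paste0(path, ".tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(as.list(metrics), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
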