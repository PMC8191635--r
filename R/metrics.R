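#' Binary-classification metrics for m6A site prediction
#'
#' Computes, from the confusion counts TP/TN/FP/FN:
#' ACC = (TP+TN)/(TP+FN+TN+FP) x 100%, SEN = TP/(TP+FN) x 100%,
#' SPE = TN/(TN+FP) x 100%, F1 = 2TP/(2TP+FP+FN),
#' MCC = (TP x TN - FP x FN) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN)),
#' plus the ROC curve and its AUC from the scores. MCC is defined as 0 when
#' any factor of its denominator is 0. AUC uses the rank (Mann-Whitney)
#' formulation, giving tied scores 0.5 credit, and equals the trapezoidal
#' area under the ROC curve. If `y_true` holds a single class, AUC is `NA`
#' with a warning; the threshold metrics are still reported.
#'
#' @param y_true Integer 0/1 reference labels.
#' @param y_pred Integer 0/1 predicted labels; defaults to
#'   `y_score >= 0.5` when scores are given.
#' @param y_score Optional probabilities of the positive class (needed for
#'   ROC/AUC).
#' @return An object of class `m6a_metrics`: a list with `acc`, `mcc`,
#'   `sen`, `spe`, `f1`, `auc`, the counts `tp`/`tn`/`fp`/`fn`, `n`, and the
#'   `roc` tibble (columns `threshold`, `fpr`, `tpr`).
#' @examples
#' compute_metrics(c(1, 1, 0, 0), c(1, 0, 0, 1), c(0.9, 0.4, 0.2, 0.6))
#' @export
compute_metrics <- function(y_true, y_pred = NULL, y_score = NULL) {
  y_true <- as.integer(y_true)
  if (is.null(y_pred)) {
    if (is.null(y_score)) abort("supply y_pred and/or y_score")
    y_pred <- as.integer(y_score >= 0.5)
  }
  y_pred <- as.integer(y_pred)
  stopifnot(length(y_true) == length(y_pred))
  if (!is.null(y_score)) stopifnot(length(y_score) == length(y_true))
  tp <- sum(y_true == 1L & y_pred == 1L)
  tn <- sum(y_true == 0L & y_pred == 0L)
  fp <- sum(y_true == 0L & y_pred == 1L)
  fn <- sum(y_true == 1L & y_pred == 0L)
  n <- tp + tn + fp + fn
  mcc_den <- prod(sqrt(c(tp + fn, tn + fp, tp + fp, tn + fn)))
  one_class <- length(unique(y_true)) < 2L
  if (one_class) warn("y_true contains a single class; AUC is undefined (NA)")
  auc <- roc <- NULL
  if (!is.null(y_score) && !one_class) {
    auc <- rank_auc(y_true, y_score)
    roc <- roc_curve(y_true, y_score)
  }
  structure(
    list(
      acc = 100 * (tp + tn) / n,
      mcc = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den,
      sen = if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn),
      spe = if (tn + fp == 0) NA_real_ else 100 * tn / (tn + fp),
      f1 = if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn),
      auc = if (is.null(auc)) NA_real_ else auc,
      tp = tp, tn = tn, fp = fp, fn = fn, n = n, roc = roc
    ),
    class = "m6a_metrics"
  )
}

rank_auc <- function(y_true, y_score) {
  # Mann-Whitney AUC; midranks give tied scores 0.5 credit
  r <- rank(y_score, ties.method = "average")
  n_pos <- sum(y_true == 1L)
  n_neg <- sum(y_true == 0L)
  (sum(r[y_true == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' One point per distinct score threshold (descending), from (0,0) to (1,1).
#' The trapezoidal area under these points equals the rank-based AUC.
#'
#' @inheritParams compute_metrics
#' @return A tibble with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(y_true, y_score) {
  y_true <- as.integer(y_true)
  n_pos <- sum(y_true == 1L)
  n_neg <- sum(y_true == 0L)
  if (n_pos == 0L || n_neg == 0L) abort("ROC needs both classes in y_true")
  ord <- order(y_score, decreasing = TRUE)
  yt <- y_true[ord]
  ys <- y_score[ord]
  keep <- !duplicated(ys, fromLast = TRUE) # last index of each distinct score
  cs_pos <- cumsum(yt == 1L)[keep]
  cs_neg <- cumsum(yt == 0L)[keep]
  tibble(
    threshold = c(Inf, ys[keep]),
    fpr = c(0, cs_neg / n_neg),
    tpr = c(0, cs_pos / n_pos)
  )
}

trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

#' @export
print.m6a_metrics <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<m6a_metrics> n = %d (TP %d, TN %d, FP %d, FN %d)\n",
      "  ACC %.2f%%  SEN %.2f%%  SPE %.2f%%  F1 %.4f  MCC %.4f  AUC %.4f\n"
    ),
    x$n, x$tp, x$tn, x$fp, x$fn, x$acc, x$sen, x$spe, x$f1, x$mcc, x$auc
  ))
  invisible(x)
}

metrics_row <- function(x) {
  tibble(
    acc = x$acc, mcc = x$mcc, sen = x$sen, spe = x$spe, f1 = x$f1,
    auc = x$auc, tp = x$tp, tn = x$tn, fp = x$fp, fn = x$fn, n = x$n
  )
}

#' Write a metrics report to JSON and TSV
#'
#' @param x An `m6a_metrics` object.
#' @param json_path,tsv_path,roc_path Optional output paths.
#' @export
write_metrics <- function(x, json_path = NULL, tsv_path = NULL, roc_path = NULL) {
  stopifnot(inherits(x, "m6a_metrics"))
  row <- metrics_row(x)
  if (!is.null(json_path)) {
    jsonlite::write_json(as.list(row), json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(row, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(roc_path) && !is.null(x$roc)) {
    utils::write.table(x$roc, roc_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(x)
}
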