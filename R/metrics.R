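#' Binary classification metrics
#'
#' Confusion counts at a score threshold plus sensitivity, specificity,
#' accuracy, Matthews correlation coefficient and AUC:
#' `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`, `ACC = (TP+TN)/n`,
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` (defined as
#' 0 when any margin is 0), and AUC by the rank (Mann-Whitney) formulation
#' with ties mid-ranked.
#'
#' @param y_true 0/1 labels.
#' @param scores predicted scores in `[0, 1]`.
#' @param threshold positive-call threshold (default 0.5).
#' @return an `m6aMetrics` object: `TP`, `TN`, `FP`, `FN`, `Sn`, `Sp`,
#'   `ACC`, `MCC`, `AUC`, `threshold`.  With a single-class `y_true` the
#'   undefined quantities are `NaN` (with a warning).
#' @export
compute_metrics <- function(y_true, scores, threshold = 0.5) {
  y_true <- as.integer(y_true)
  scores <- as.numeric(scores)
  if (length(y_true) != length(scores)) stop("length mismatch")
  if (any(!y_true %in% c(0L, 1L))) stop("y_true must be 0/1")
  pred <- as.integer(scores >= threshold)
  TP <- sum(pred == 1L & y_true == 1L)
  TN <- sum(pred == 0L & y_true == 0L)
  FP <- sum(pred == 1L & y_true == 0L)
  FN <- sum(pred == 0L & y_true == 1L)
  n_pos <- TP + FN
  n_neg <- TN + FP
  if (n_pos == 0L || n_neg == 0L)
    warning("single-class y_true: Sn/Sp/AUC partially undefined (NaN)")
  Sn <- if (n_pos > 0L) TP / n_pos else NaN
  Sp <- if (n_neg > 0L) TN / n_neg else NaN
  ACC <- (TP + TN) / length(y_true)
  denom <- as.numeric(TP + FP) * as.numeric(TP + FN) *
    as.numeric(TN + FP) * as.numeric(TN + FN)
  MCC <- if (denom == 0) 0 else
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(denom)
  AUC <- auc_rank(y_true, scores)
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 Sn = Sn, Sp = Sp, ACC = ACC, MCC = MCC, AUC = AUC,
                 threshold = threshold),
            class = "m6aMetrics")
}

# Mann-Whitney AUC with mid-ranked ties; NaN if a class is absent.
auc_rank <- function(y_true, scores) {
  n_pos <- sum(y_true == 1L)
  n_neg <- sum(y_true == 0L)
  if (n_pos == 0L || n_neg == 0L) return(NaN)
  r <- rank(scores, ties.method = "average")
  (sum(r[y_true == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' @export
print.m6aMetrics <- function(x, ...) {
  cat(sprintf(
    "m6aMetrics @ %.2f: ACC %.4f  Sn %.4f  Sp %.4f  MCC %.4f  AUC %.4f  (TP %d TN %d FP %d FN %d)\n",
    x$threshold, x$ACC, x$Sn, x$Sp, x$MCC, x$AUC, x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' @export
as.data.frame.m6aMetrics <- function(x, ...) {
  data.frame(TP = x$TP, TN = x$TN, FP = x$FP, FN = x$FN, Sn = x$Sn,
             Sp = x$Sp, ACC = x$ACC, MCC = x$MCC, AUC = x$AUC,
             threshold = x$threshold)
}

#' ROC curve points
#'
#' @param y_true 0/1 labels.
#' @param scores predicted scores.
#' @return data frame of (threshold, FPR, TPR) suitable for plotting or TSV
#'   export.
#' @export
roc_points <- function(y_true, scores) {
  ord <- order(scores, decreasing = TRUE)
  y <- as.integer(y_true)[ord]
  s <- as.numeric(scores)[ord]
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  tpr <- cumsum(y == 1L) / n_pos
  fpr <- cumsum(y == 0L) / n_neg
  keep <- !duplicated(s, fromLast = TRUE)
  data.frame(threshold = c(Inf, s[keep]),
             FPR = c(0, fpr[keep]),
             TPR = c(0, tpr[keep]))
}
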