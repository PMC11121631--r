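#' Confusion matrix over the eight localization classes
#'
#' `Z[i, j]` counts proteins observed in class `i` and predicted in class
#' `j`, rows and columns in frozen class order.
#'
#' @param pred character vector of predicted class names (or 0-based integer
#'   indices).
#' @param obs character vector of observed class names (same length).
#' @return 8 x 8 integer matrix with class dimnames.
#' @export
confusion <- function(pred, obs) {
  if (length(pred) != length(obs)) {
    stop("pred (", length(pred), ") and obs (", length(obs),
         ") differ in length")
  }
  to_factor <- function(x) {
    if (is.numeric(x)) x <- .CLASSES[x + 1L]
    factor(normalize_class(x), levels = .CLASSES)
  }
  Z <- table(obs = to_factor(obs), pred = to_factor(pred))
  m <- matrix(as.integer(Z), 8L, 8L,
              dimnames = list(observed = .CLASSES, predicted = .CLASSES))
  m
}

#' Per-class one-vs-rest metrics from a confusion matrix
#'
#' For each class i: `TP = Z[i,i]`, `FP = sum(Z[-i, i])` (predicted i,
#' observed elsewhere), `FN = sum(Z[i, -i])`, `TN` the rest. From these:
#'
#' * `Spec = TP / (TP + FP)` — note this is the positive predictive value
#'   (precision); it is reported under this name for continuity with the
#'   field's reporting convention, with textbook specificity
#'   `TN / (TN + FP)` additionally provided as `TrueSpec`.
#' * `Sens = TP / (TP + FN)`
#' * `Acc  = (TP + TN) / (TP + TN + FP + FN)`
#' * `MCC  = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`
#' * `F1   = 2 * Spec * Sens / (Spec + Sens)` (harmonic mean of precision
#'   and sensitivity)
#'
#' Any metric with a zero denominator is defined as 0 and flagged in the
#' `degenerate` column.
#'
#' @param Z 8 x 8 confusion matrix from [confusion()].
#' @return data frame with one row per class: counts, metrics, `degenerate`.
#' @export
per_class_metrics <- function(Z) {
  Z <- as.matrix(Z)
  stopifnot(nrow(Z) == 8L, ncol(Z) == 8L, all(Z >= 0))
  total <- sum(Z)
  rows <- lapply(seq_len(8L), function(i) {
    TP <- Z[i, i]
    FP <- sum(Z[-i, i])
    FN <- sum(Z[i, -i])
    TN <- total - TP - FP - FN
    safe <- function(num, den) if (den == 0) 0 else num / den
    spec <- safe(TP, TP + FP)
    sens <- safe(TP, TP + FN)
    acc <- safe(TP + TN, total)
    mcc_den <- sqrt(as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
    mcc <- if (mcc_den == 0) 0 else
      (as.numeric(TP) * TN - as.numeric(FP) * FN) / mcc_den
    f1 <- safe(2 * spec * sens, spec + sens)
    truespec <- safe(TN, TN + FP)
    degenerate <- (TP + FP) == 0 || (TP + FN) == 0 || mcc_den == 0
    data.frame(class = .CLASSES[i], TP = TP, FP = FP, TN = TN, FN = FN,
               Spec = spec, Sens = sens, Acc = acc, MCC = mcc, F1 = f1,
               TrueSpec = truespec, degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Overall accuracy Q
#'
#' Trace of the confusion matrix over its grand total: the fraction of
#' proteins predicted in their observed class.
#'
#' @param Z confusion matrix.
#' @return Q in `[0, 1]`.
#' @export
overall_Q <- function(Z) {
  Z <- as.matrix(Z)
  if (sum(Z) == 0) stop("confusion matrix is empty (no evaluated proteins)")
  sum(diag(Z)) / sum(Z)
}

#' Formatted per-class performance report
#'
#' One row per class in frozen order, with MCC to 2 decimals and the
#' percentage metrics to 2 decimals, plus the overall Q.
#'
#' @param Z confusion matrix.
#' @param path optional path; when given the table is also written as TSV.
#' @return data frame with formatted columns; attribute `Q` holds the
#'   overall accuracy.
#' @export
metrics_report <- function(Z, path = NULL) {
  m <- per_class_metrics(Z)
  out <- data.frame(
    class = m$class,
    MCC = sprintf("%.2f", m$MCC),
    Accuracy = sprintf("%.2f%%", 100 * m$Acc),
    Spec = sprintf("%.2f%%", 100 * m$Spec),
    Sens = sprintf("%.2f%%", 100 * m$Sens),
    F1 = sprintf("%.2f%%", 100 * m$F1),
    TrueSpec = sprintf("%.2f%%", 100 * m$TrueSpec),
    stringsAsFactors = FALSE)
  attr(out, "Q") <- overall_Q(Z)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}
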