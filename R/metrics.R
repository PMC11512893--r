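## Confusion-matrix metrics and multiclass ROC analysis.

#' Confusion counts for multiclass predictions
#'
#' @param truth,pred vectors of class labels (character or factor) or
#'   integer class ids.
#' @param classes ordered class levels.
#' @return object of class `confusion_counts`: the K x K matrix
#'   (rows = truth, columns = predicted) and the per-class one-vs-rest
#'   TP/TN/FP/FN counts derived from it.
#' @export
confusion_counts <- function(truth, pred, classes = CLASS_LEVELS) {
  t_f <- factor(as.character(truth), levels = classes)
  p_f <- factor(as.character(pred), levels = classes)
  if (anyNA(t_f) || anyNA(p_f))
    stop_arg("labels outside the declared class set")
  m <- table(truth = t_f, predicted = p_f)
  n <- sum(m)
  per <- lapply(seq_along(classes), function(k) {
    tp <- m[k, k]
    fn <- sum(m[k, ]) - tp
    fp <- sum(m[, k]) - tp
    tn <- n - tp - fn - fp
    c(tp = tp, tn = tn, fp = fp, fn = fn)
  })
  names(per) <- classes
  structure(list(matrix = unclass(m), per_class = per, n = n,
                 classes = classes),
            class = "confusion_counts")
}

ratio_or_zero <- function(num, den) {
  if (den == 0) structure(0, flagged = TRUE) else num / den
}

#' Classification metrics from confusion counts
#'
#' One-vs-rest accuracy, sensitivity (recall), specificity, precision and
#' F1 per class, plus unweighted macro averages, all as percentages.
#' Zero-denominator metrics are reported as 0 and flagged rather than
#' raised, so fold aggregation always totals.
#'
#' @param counts a [confusion_counts()] object.
#' @return object of class `eval_report`: `per_class` (data frame) and
#'   `macro` (named percentages), plus `overall_accuracy` (fraction of
#'   correctly classified samples, %).
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  rows <- lapply(counts$classes, function(cl) {
    ct <- counts$per_class[[cl]]
    tp <- ct["tp"]; tn <- ct["tn"]; fp <- ct["fp"]; fn <- ct["fn"]
    acc <- ratio_or_zero(tp + tn, tp + tn + fp + fn)
    sens <- ratio_or_zero(tp, tp + fn)
    prec <- ratio_or_zero(tp, tp + fp)
    spec <- ratio_or_zero(tn, tn + fp)
    f1 <- if (prec + sens == 0) structure(0, flagged = TRUE)
          else 2 * prec * sens / (prec + sens)
    flagged <- any(vapply(list(acc, sens, prec, spec, f1),
                          function(x) isTRUE(attr(x, "flagged")), TRUE))
    data.frame(class = cl, accuracy = 100 * as.numeric(acc),
               sensitivity = 100 * as.numeric(sens),
               specificity = 100 * as.numeric(spec),
               precision = 100 * as.numeric(prec),
               f1 = 100 * as.numeric(f1), flagged = flagged)
  })
  per <- do.call(rbind, rows)
  macro <- c(accuracy = mean(per$accuracy),
             sensitivity = mean(per$sensitivity),
             specificity = mean(per$specificity),
             precision = mean(per$precision),
             f1 = mean(per$f1))
  overall <- 100 * sum(diag(counts$matrix)) / counts$n
  structure(list(per_class = per, macro = macro,
                 overall_accuracy = overall,
                 confusion = counts$matrix),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Evaluation report (percent)\n")
  print(round(x$per_class[, 1:6], 2), row.names = FALSE)
  cat("macro:", paste(sprintf("%s=%.2f", names(x$macro), x$macro),
                      collapse = "  "), "\n")
  cat(sprintf("overall accuracy: %.2f%%\n", x$overall_accuracy))
  invisible(x)
}

## binary ROC by threshold sweep; returns fpr/tpr (including endpoints)
binary_roc <- function(truth01, score) {
  o <- order(score, decreasing = TRUE)
  t_s <- truth01[o]
  tp <- cumsum(t_s); fp <- cumsum(1 - t_s)
  P <- sum(t_s); N <- length(t_s) - P
  if (P == 0 || N == 0) return(NULL)
  # one point per distinct threshold
  keep <- c(diff(score[o]) != 0, TRUE)
  tpr <- c(0, tp[keep] / P); fpr <- c(0, fp[keep] / N)
  list(fpr = fpr, tpr = tpr, auc = sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2))
}

#' One-vs-rest, micro- and macro-averaged ROC curves
#'
#' Per class, the ROC of that class's probability against the one-vs-rest
#' truth with trapezoidal AUC; the micro average pools every
#' (sample, class) decision; the macro curve averages per-class TPR on a
#' common FPR grid and the macro AUC is the unweighted mean of the
#' per-class AUCs.  A class absent from the truth yields `NA` AUC.
#'
#' @param truth vector of true labels.
#' @param probs N x K matrix of class probabilities (rows sum to 1).
#' @param classes ordered class levels (defaults to `colnames(probs)`).
#' @return list with `per_class` (each `fpr`, `tpr`, `auc`), `micro`,
#'   `macro`, and `auc` (named vector of per-class + micro + macro AUCs).
#' @export
roc_curves <- function(truth, probs, classes = colnames(probs)) {
  if (is.null(classes)) classes <- CLASS_LEVELS[seq_len(ncol(probs))]
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop_arg("probability rows must sum to 1")
  truth <- as.character(truth)
  per <- list()
  for (k in seq_along(classes)) {
    per[[classes[k]]] <- binary_roc(as.numeric(truth == classes[k]), probs[, k])
  }
  onehot <- outer(truth, classes, `==`) * 1
  micro <- binary_roc(as.vector(onehot), as.vector(probs))
  aucs <- vapply(per, function(p) if (is.null(p)) NA_real_ else p$auc, 0)
  grid <- sort(unique(c(0, 1, unlist(lapply(per, function(p) p$fpr)))))
  tprs <- vapply(per[!vapply(per, is.null, TRUE)], function(p)
    stats::approx(p$fpr, p$tpr, xout = grid, ties = max, rule = 2)$y,
    numeric(length(grid)))
  macro <- list(fpr = grid,
                tpr = if (is.matrix(tprs)) rowMeans(tprs) else tprs,
                auc = mean(aucs, na.rm = TRUE))
  list(per_class = per, micro = micro, macro = macro,
       auc = c(aucs, micro = micro$auc, macro = macro$auc))
}
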