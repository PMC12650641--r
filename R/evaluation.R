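# Evaluation metrics: accuracy, F1, Cohen's kappa, micro-averaged ROC AUC,
# normalised confusion matrices, and mean +/- sd aggregation across
# folds/runs with paired-test utilities for the ablation harness.

#' Confusion matrix
#'
#' @param y_true,y_pred integer class labels (1..n_classes).
#' @param n_classes number of classes.
#' @return (n_classes x n_classes) count matrix, rows = true, cols = predicted.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes = max(y_true, y_pred)) {
  stopifnot(length(y_true) == length(y_pred))
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(y_true)) {
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  }
  cm
}

#' Accuracy from a confusion matrix
#'
#' Fraction of correctly classified samples (trace over total).
#'
#' @param cm confusion matrix (rows = true, cols = predicted).
#' @return Accuracy in [0, 1].
#' @export
accuracy_score <- function(cm) {
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  sum(diag(cm)) / n
}

#' F1 score from a confusion matrix
#'
#' Per class, \eqn{F1 = TP / (TP + (FP + FN) / 2)}. Multiclass scores are
#' macro-averaged (unweighted class mean). A class with neither true nor
#' predicted samples contributes an F1 of 0.
#'
#' @param cm confusion matrix.
#' @param average `"macro"` or `"binary"`.
#' @param positive positive-class index for binary averaging.
#' @return F1 in [0, 1].
#' @export
f1_score <- function(cm, average = c("macro", "binary"), positive = 2L) {
  average <- match.arg(average)
  per_class <- function(k) {
    tp <- cm[k, k]
    fp <- sum(cm[-k, k])
    fn <- sum(cm[k, -k])
    denom <- tp + (fp + fn) / 2
    if (denom == 0) 0 else tp / denom
  }
  if (average == "binary") {
    per_class(positive)
  } else {
    mean(vapply(seq_len(nrow(cm)), per_class, numeric(1)))
  }
}

#' Cohen's kappa from a confusion matrix
#'
#' \eqn{\kappa = (P_0 - P_e) / (1 - P_e)} with \eqn{P_0} the observed
#' accuracy and \eqn{P_e} the chance agreement from the marginals.
#'
#' @param cm confusion matrix.
#' @return Kappa in [-1, 1].
#' @export
cohen_kappa <- function(cm) {
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  p0 <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe >= 1) {
    stop("degenerate confusion matrix: chance agreement is 1, kappa undefined")
  }
  (p0 - pe) / (1 - pe)
}

#' Micro-averaged one-vs-rest ROC AUC
#'
#' Flattens all (sample, class) pairs into a single binary problem (score =
#' predicted probability, label = class indicator) and integrates the ROC
#' curve by the trapezoidal rule; equivalent to the pairwise concordance
#' statistic on the flattened scores.
#'
#' @param scores (n, C) matrix of per-class probability scores.
#' @param labels integer labels 1..C.
#' @return AUC in [0, 1].
#' @export
roc_auc_micro <- function(scores, labels) {
  scores <- as.matrix(scores)
  C <- ncol(scores)
  if (length(unique(labels)) < 2) {
    stop("single-class labels: ROC undefined")
  }
  onehot <- matrix(0L, nrow(scores), C)
  onehot[cbind(seq_len(nrow(scores)), labels)] <- 1L
  s <- as.vector(scores)
  b <- as.vector(onehot)
  ord <- order(s, decreasing = TRUE)
  b <- b[ord]
  s <- s[ord]
  np <- sum(b == 1)
  nn <- sum(b == 0)
  tp <- cumsum(b == 1)
  fp <- cumsum(b == 0)
  # collapse score ties to the last point of each tied block
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, tp[keep] / np)
  fpr <- c(0, fp[keep] / nn)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Evaluate predictions into a report
#'
#' @param probs (n, C) probability matrix.
#' @param labels integer labels 1..C.
#' @return list of class `"evaluation_report"`: `accuracy`, `f1` (macro),
#'   `kappa`, `auc`, `confusion`, `n`.
#' @export
evaluation_report <- function(probs, labels) {
  pred <- max.col(as.matrix(probs), ties.method = "first")
  cm <- confusion_matrix(labels, pred, n_classes = ncol(probs))
  rep <- list(accuracy = accuracy_score(cm), f1 = f1_score(cm),
              kappa = cohen_kappa(cm),
              auc = tryCatch(roc_auc_micro(probs, labels),
                             error = function(e) NA_real_),
              confusion = cm, n = length(labels))
  class(rep) <- "evaluation_report"
  rep
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f  macro-F1 %.4f  kappa %.4f  micro-AUC %s  (n = %d)\n",
              x$accuracy, x$f1, x$kappa,
              if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc), x$n))
  invisible(x)
}

#' Row-normalised confusion matrix
#'
#' @param cm count matrix.
#' @return Matrix of per-true-class proportions (rows sum to 1).
#' @export
normalize_confusion <- function(cm) {
  rs <- rowSums(cm)
  rs[rs == 0] <- 1
  cm / rs
}

#' Aggregate evaluation reports across folds or runs
#'
#' Means and sample standard deviations (n - 1 denominator) per metric,
#' a t-based 95% confidence interval for accuracy, and the confusion
#' matrices summed then row-normalised.
#'
#' @param reports list of `evaluation_report` objects.
#' @return list with `mean`, `sd`, `ci95` (accuracy), `confusion`
#'   (normalised aggregate), `n_runs`, `per_run` (data.frame).
#' @export
aggregate_runs <- function(reports) {
  stopifnot(length(reports) >= 1)
  met <- c("accuracy", "f1", "kappa", "auc")
  per <- as.data.frame(lapply(met, function(m) {
    vapply(reports, function(r) r[[m]], numeric(1))
  }))
  names(per) <- met
  mu <- colMeans(per)
  sdv <- if (nrow(per) > 1) apply(per, 2, stats::sd) else {
    stats::setNames(rep(0, length(met)), met)
  }
  k <- nrow(per)
  ci <- if (k > 1 && sdv["accuracy"] > 0) {
    mu["accuracy"] + c(-1, 1) * stats::qt(0.975, k - 1) * sdv["accuracy"] / sqrt(k)
  } else {
    rep(mu["accuracy"], 2)
  }
  cm <- Reduce(`+`, lapply(reports, `[[`, "confusion"))
  list(mean = mu, sd = sdv, ci95 = ci, confusion = normalize_confusion(cm),
       n_runs = k, per_run = per)
}

#' Paired comparison of two accuracy vectors
#'
#' Paired t-test or Wilcoxon signed-rank test over matched folds/runs.
#' Identical vectors give p = 1 (zero mean difference).
#'
#' @param a,b numeric metric vectors of equal length (matched pairs).
#' @param method `"t"` or `"wilcoxon"`.
#' @return list with `p_value`, `mean_diff`, `method`.
#' @export
paired_comparison <- function(a, b, method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  stopifnot(length(a) == length(b))
  d <- a - b
  p <- if (all(d == 0)) {
    1
  } else if (stats::sd(d) == 0) {
    # constant non-zero difference: degenerate paired t, effectively certain
    0
  } else if (method == "t") {
    stats::t.test(a, b, paired = TRUE)$p.value
  } else {
    suppressWarnings(stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value)
  }
  list(p_value = p, mean_diff = mean(d), method = method)
}
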