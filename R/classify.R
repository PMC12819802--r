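#' Rank-based AUC (Mann-Whitney)
#'
#' Area under the ROC curve computed from the rank-sum formulation with
#' midrank tie handling: the probability that a random positive scores above
#' a random negative, counting ties as 1/2.
#'
#' @param scores Numeric decision scores (higher = more positive).
#' @param labels Logical or two-level vector; the second factor level (or
#'   `TRUE`) is the positive class.
#' @return AUC in \eqn{[0, 1]}.
#' @export
#' @examples
#' auc_rank(c(0.1, 0.4, 0.35, 0.8), c(FALSE, TRUE, FALSE, TRUE))
auc_rank <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == levels(factor(labels))[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  stop_not(n1 > 0 && n0 > 0, "both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix classification metrics
#'
#' Computes sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), accuracy =
#' (TP+TN)/N and precision = TP/(TP+FP), reported in percent, plus the
#' rank-based AUC when decision scores are supplied. A zero denominator
#' yields `NA`, not 0.
#'
#' @param tp,fn,tn,fp Nonnegative integer confusion counts.
#' @param scores Optional decision scores for AUC.
#' @param labels Optional labels aligned with `scores`.
#' @return A tibble (tp, fn, tn, fp, sensitivity, specificity, accuracy,
#'   precision, auc), percentages on the 0-100 scale, AUC in \eqn{[0, 1]}.
#' @export
#' @examples
#' classification_metrics(36, 10, 25, 12)
classification_metrics <- function(tp, fn, tn, fp, scores = NULL,
                                   labels = NULL) {
  counts <- c(tp, fn, tn, fp)
  stop_not(all(counts >= 0) && all(counts == round(counts)),
           "counts must be nonnegative integers")
  rate <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  auc <- if (!is.null(scores)) auc_rank(scores, labels) else NA_real_
  tibble(
    tp = tp, fn = fn, tn = tn, fp = fp,
    sensitivity = rate(tp, tp + fn),
    specificity = rate(tn, tn + fp),
    accuracy = rate(tp + tn, sum(counts)),
    precision = rate(tp, tp + fp),
    auc = auc
  )
}

#' Leave-one-out cross-validated linear SVM
#'
#' N-fold LOOCV of a linear maximum-margin classifier: in each fold the
#' features are standardized on the training subjects only, a linear SVM
#' (cost `cost`) is fitted, and the held-out subject's decision score and
#' predicted class are recorded. Confusion counts accumulate over folds; the
#' ROC/AUC is built from the pooled held-out decision scores; features are
#' ranked by mean absolute weight across folds. Constant features (in any
#' training fold) are dropped with a warning.
#'
#' @param features Subjects x features numeric matrix or data frame.
#' @param labels Two-level vector; the second factor level is the positive
#'   class.
#' @param cost SVM regularization constant (default 1).
#' @return A `loocv_report`: `metrics` (tibble from
#'   [classification_metrics()]), `scores` (tibble subject, label, score,
#'   predicted), `feature_ranking` (tibble feature, mean_abs_weight, rank),
#'   `folds`.
#' @export
loocv_classify <- function(features, labels, cost = 1) {
  x <- as.matrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- factor(labels)
  n <- nrow(x)
  stop_not(n >= 6, "need at least 6 subjects for LOOCV")
  stop_not(nlevels(y) == 2, "`labels` must have exactly two levels")
  stop_not(length(y) == n, "labels and features disagree in length")
  const <- apply(x, 2, function(v) sd(v) < 1e-12)
  if (any(const)) {
    warn(sprintf("dropping constant feature(s): %s",
                 paste(colnames(x)[const], collapse = ", ")))
    x <- x[, !const, drop = FALSE]
  }
  pos <- levels(y)[2]
  scores <- numeric(n)
  pred <- character(n)
  wabs <- matrix(0, n, ncol(x), dimnames = list(NULL, colnames(x)))
  for (i in seq_len(n)) {
    tr_x <- x[-i, , drop = FALSE]
    tr_y <- y[-i]
    stop_not(nlevels(droplevels(tr_y)) == 2,
             "a class is absent from training fold %d", i)
    mu <- colMeans(tr_x)
    sg <- apply(tr_x, 2, sd)
    sg[sg < 1e-12] <- 1
    tr_s <- sweep(sweep(tr_x, 2, mu), 2, sg, `/`)
    te_s <- (x[i, ] - mu) / sg
    fit <- e1071::svm(tr_s, tr_y, kernel = "linear", cost = cost,
                      scale = FALSE)
    dv <- attr(predict(fit, rbind(te_s), decision.values = TRUE),
               "decision.values")
    # e1071 orients the decision value toward the first class in "A/B"
    flip <- if (grepl(paste0("^", pos, "/"), colnames(dv)[1])) 1 else -1
    scores[i] <- flip * dv[1]
    pred[i] <- as.character(predict(fit, rbind(te_s)))
    w <- crossprod(fit$coefs, fit$SV)
    wabs[i, ] <- abs(as.vector(w))
  }
  tp <- sum(pred == pos & y == pos)
  fn <- sum(pred != pos & y == pos)
  tn <- sum(pred != pos & y != pos)
  fp <- sum(pred == pos & y != pos)
  metrics <- classification_metrics(tp, fn, tn, fp, scores = scores,
                                    labels = y)
  ranking <- tibble(feature = colnames(x),
                    mean_abs_weight = colMeans(wabs))
  ranking <- dplyr::arrange(ranking, dplyr::desc(.data$mean_abs_weight))
  ranking$rank <- seq_len(nrow(ranking))
  structure(list(metrics = metrics,
                 scores = tibble(subject = rownames(x) %||% as.character(seq_len(n)),
                                 label = as.character(y), score = scores,
                                 predicted = pred),
                 feature_ranking = ranking, folds = n, cost = cost),
            class = "loocv_report")
}

#' @export
print.loocv_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<loocv_report> %d folds; accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%, AUC %.3f\n",
              x$folds, m$accuracy, m$sensitivity, m$specificity, m$auc))
  invisible(x)
}

#' ROC curve points from held-out scores
#'
#' Sweeps every threshold over the pooled LOOCV decision scores and returns
#' the (false positive rate, true positive rate) pairs.
#'
#' @param report A `loocv_report`.
#' @return A tibble (threshold, fpr, tpr) ordered for plotting.
#' @export
roc_points <- function(report) {
  stop_not(inherits(report, "loocv_report"), "`report` must be a loocv_report")
  s <- report$scores
  pos <- s$label == levels(factor(s$label))[2]
  thr <- c(Inf, sort(unique(s$score), decreasing = TRUE), -Inf)
  tibble(
    threshold = thr,
    fpr = vapply(thr, function(t0) mean(s$score[!pos] >= t0), numeric(1)),
    tpr = vapply(thr, function(t0) mean(s$score[pos] >= t0), numeric(1))
  )
}
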