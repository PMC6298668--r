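#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores in descending order;
#' tied scores move their true- and false-positive counts simultaneously
#' (equivalent to the mid-rank convention for the pairwise rank statistic).
#' The AUC is the trapezoidal area under the resulting curve, which equals
#' the probability that a randomly chosen positive is ranked above a randomly
#' chosen negative.
#'
#' @param scores numeric decision scores, higher = more positive.
#' @param labels logical (or coercible) vector, `TRUE` = positive; both
#'   classes must be present.
#' @return a list of class `roc_curve` with `thresholds` (descending),
#'   `tpr`, `fpr` (each starting at 0 and ending at 1) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0L || nn == 0L) stop("both classes must be present to build a ROC curve")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  grp <- cumsum(c(TRUE, diff(s) != 0))        # runs of tied scores
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- which(c(diff(grp) != 0, TRUE))       # last index of each tie group
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, s[last]), tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.4f\n", length(x$tpr), x$auc))
  invisible(x)
}

#' Recall-precision trade-off curve
#'
#' Recall and precision at every threshold of the empirical score
#' distribution (predict positive when score >= threshold), from the
#' all-negative operating point (recall 0; precision emitted as 1 by
#' convention) down to the all-positive one (recall 1, precision =
#' prevalence).
#'
#' @inheritParams roc_auc
#' @return data.frame with columns `threshold`, `recall`, `precision`.
#' @export
pr_tradeoff <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0L || nn == 0L) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  grp <- cumsum(c(TRUE, diff(s) != 0))
  last <- which(c(diff(grp) != 0, TRUE))
  tp <- cumsum(l)[last]; pred_pos <- last
  data.frame(threshold = c(Inf, s[last]),
             recall = c(0, tp / np),
             precision = c(1, tp / pred_pos))
}

#' F score (harmonic mean of recall and precision)
#'
#' @param recall,precision values in `[0, 1]`; `(0, 0)` yields 0 by
#'   convention.
#' @return the F score `2 R P / (R + P)`.
#' @export
f_score <- function(recall, precision) {
  if (any(recall < 0 | recall > 1) || any(precision < 0 | precision > 1))
    stop("recall and precision must lie in [0, 1]")
  ifelse(recall + precision == 0, 0, 2 * recall * precision / (recall + precision))
}

#' Operating point and F score of a score vector
#'
#' Scans the recall-precision curve and reports the recall, precision and F
#' score either at the F-maximizing threshold (`threshold = "max_f"`, the
#' default) or at a fixed decision threshold (`threshold = 0` corresponds to
#' the SVM margin).
#'
#' @inheritParams roc_auc
#' @param threshold `"max_f"` or a numeric threshold (predict positive at
#'   score >= threshold).
#' @return named numeric: `recall`, `precision`, `f`, `threshold`.
#' @export
report_f <- function(scores, labels, threshold = "max_f") {
  labels <- as.logical(labels)
  if (identical(threshold, "max_f")) {
    pr <- pr_tradeoff(scores, labels)
    f <- f_score(pr$recall, pr$precision)
    i <- which.max(f)
    c(recall = pr$recall[i], precision = pr$precision[i], f = f[i],
      threshold = pr$threshold[i])
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L)
    pred <- scores >= threshold
    tp <- sum(pred & labels)
    r <- tp / sum(labels)
    p <- if (sum(pred) == 0L) 1 else tp / sum(pred)
    c(recall = r, precision = p, f = f_score(r, p), threshold = threshold)
  }
}

#' Confusion matrix
#'
#' Rows are the true (visually assigned) classes and columns the predicted
#' classes.
#'
#' @param true_labels,predicted_labels equal-length label vectors; every
#'   value must appear in `classes`.
#' @param classes ordered class labels (default: sorted union of the truth).
#' @return integer `k x k` matrix with dimnames `true` x `predicted`.
#' @export
confusion_matrix <- function(true_labels, predicted_labels,
                             classes = sort(unique(true_labels))) {
  stopifnot(length(true_labels) == length(predicted_labels))
  if (!all(true_labels %in% classes) || !all(predicted_labels %in% classes))
    stop("label outside the declared classes")
  tt <- factor(true_labels, levels = classes)
  pp <- factor(predicted_labels, levels = classes)
  m <- table(true = tt, predicted = pp)
  matrix(as.integer(m), nrow = length(classes),
         dimnames = list(true = classes, predicted = classes))
}

#' Evaluation report for one test split
#'
#' Bundles the test-set ROC/AUC, recall-precision curve and F-score operating
#' point of a scored binary problem.
#'
#' @inheritParams roc_auc
#' @param threshold passed to [report_f()].
#' @return a list of class `eval_report` with `auc`, `roc`, `pr_curve`,
#'   `recall`, `precision`, `f_score`, `n_test`.
#' @export
eval_report <- function(scores, labels, threshold = "max_f") {
  labels <- as.logical(labels)
  roc <- roc_auc(scores, labels)
  fp <- report_f(scores, labels, threshold)
  structure(list(auc = roc$auc, roc = roc,
                 pr_curve = pr_tradeoff(scores, labels),
                 recall = unname(fp["recall"]), precision = unname(fp["precision"]),
                 f_score = unname(fp["f"]), n_test = length(labels)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d, AUC = %.3f, F = %.3f (recall %.3f, precision %.3f)\n",
              x$n_test, x$auc, x$f_score, x$recall, x$precision))
  invisible(x)
}

#' Median aggregation of repeated-split reports
#'
#' All headline metrics are reported as medians over the repeated random
#' test splits.
#'
#' @param reports non-empty list of `eval_report`s (or of named numeric
#'   vectors with common names).
#' @return named numeric vector of per-metric medians.
#' @export
aggregate_reports <- function(reports) {
  if (length(reports) == 0L) stop("no reports to aggregate")
  if (inherits(reports[[1]], "eval_report")) {
    grab <- function(f) stats::median(vapply(reports, function(r) r[[f]], numeric(1)))
    return(c(auc = grab("auc"), f_score = grab("f_score"),
             recall = grab("recall"), precision = grab("precision")))
  }
  mats <- do.call(rbind, lapply(reports, unlist))
  apply(mats, 2, stats::median)
}
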