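# Classifier evaluation metrics (sensitivity, specificity, precision,
# accuracy, F1, AP, AUC, weighted averages) and the human-AI agreement
# statistics for paired timing series (ICC(A,1), Bland-Altman, Pearson r,
# Wilcoxon signed-rank).

#' One-vs-rest confusion counts
#'
#' @param tp,tn,fp,fn non-negative counts.
#' @return list of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(v < 0) || anyNA(v)) stop("counts must be non-negative", call. = FALSE)
  if (sum(v) == 0) stop("all-zero confusion counts", call. = FALSE)
  structure(as.list(v), class = "confusion_counts")
}

# guarded ratio: 0 with a flag when the denominator is empty
.safe_ratio <- function(num, den) {
  if (den == 0) structure(0, undefined = TRUE) else num / den
}

#' Scalar classification metrics from confusion counts
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), precision =
#' TP/(TP+FP), accuracy = (TP+TN)/total and F1 = 2 P S / (P + S) (the
#' harmonic mean of precision and sensitivity). A metric whose denominator
#' is empty is reported as 0 and flagged in the `undefined` field.
#'
#' @param counts a [confusion_counts()] (or tp/tn/fp/fn passed on to it).
#' @return list with `sensitivity, specificity, precision, accuracy, f1`
#'   (proportions in `[0, 1]`) and `undefined` (character vector of flagged
#'   metrics).
#' @export
class_metrics <- function(counts) {
  if (!inherits(counts, "confusion_counts")) counts <- do.call(confusion_counts, as.list(counts))
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  sens <- .safe_ratio(tp, tp + fn)
  spec <- .safe_ratio(tn, tn + fp)
  prec <- .safe_ratio(tp, tp + fp)
  acc <- (tp + tn) / (tp + tn + fp + fn)
  f1 <- if (prec + sens == 0) structure(0, undefined = TRUE) else
    2 * prec * sens / (prec + sens)
  vals <- list(sensitivity = sens, specificity = spec, precision = prec,
               accuracy = acc, f1 = f1)
  undefined <- names(vals)[vapply(vals, function(x) isTRUE(attr(x, "undefined")), logical(1))]
  vals <- lapply(vals, as.numeric)
  c(vals, list(undefined = undefined))
}

#' F1 score from precision and sensitivity
#'
#' Harmonic mean on whatever scale the inputs share (proportions or
#' percentages).
#'
#' @param precision,sensitivity same-scale values.
#' @return F1 on that scale.
#' @export
f1_score <- function(precision, sensitivity) {
  if (precision + sensitivity == 0) return(0)
  2 * precision * sensitivity / (precision + sensitivity)
}

#' Sample-weighted average of per-class metric values
#'
#' Weights are normalized internally from class sample counts, giving
#' greater weight to classes with larger sample sizes.
#'
#' @param values per-class metric values.
#' @param weights per-class weights or sample counts (same length).
#' @return scalar weighted average.
#' @export
weighted_average <- function(values, weights) {
  if (length(values) != length(weights))
    stop("values and weights differ in length", call. = FALSE)
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative and not all zero", call. = FALSE)
  sum(values * weights / sum(weights))
}

# descending-score threshold sweep shared by ROC and PR; ties grouped
.sweep <- function(scores, truth) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- truth[o]
  keep <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie group
  data.frame(tp = cumsum(y)[keep], fp = cumsum(!y)[keep])
}

#' ROC curve and trapezoidal AUC
#'
#' Builds the ROC curve by descending-score thresholding (ties grouped at a
#' single threshold) and integrates the area with the trapezoid rule over
#' (FPR, TPR). Equals the Mann-Whitney pairwise-comparison probability.
#'
#' @param scores numeric scores (higher = more positive).
#' @param truth logical (or 0/1) class membership; both classes required.
#' @return list with `points` (data frame `fpr, tpr`) and `auc`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth) || anyNA(scores) || anyNA(truth))
    stop("scores and truth must be complete and equal-length", call. = FALSE)
  np <- sum(truth); nn <- sum(!truth)
  if (np == 0 || nn == 0)
    stop("ROC needs at least one positive and one negative", call. = FALSE)
  sw <- .sweep(scores, truth)
  fpr <- c(0, sw$fp / nn); tpr <- c(0, sw$tp / np)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Precision-recall curve and trapezoidal average precision
#'
#' Builds the PR curve by descending-score thresholding (ties grouped) and
#' integrates precision over recall with the trapezoid rule - the direct
#' discretization of AP as the area under p(r).
#'
#' @param scores numeric scores.
#' @param truth logical (or 0/1) class membership; at least one positive.
#' @return list with `points` (data frame `recall, precision`) and `ap`.
#' @export
pr_ap <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth) || anyNA(scores) || anyNA(truth))
    stop("scores and truth must be complete and equal-length", call. = FALSE)
  np <- sum(truth)
  if (np == 0) stop("PR curve needs at least one positive", call. = FALSE)
  sw <- .sweep(scores, truth)
  recall <- sw$tp / np
  precision <- sw$tp / (sw$tp + sw$fp)
  # anchor at recall 0 with the first threshold's precision
  recall <- c(0, recall); precision <- c(precision[1], precision)
  ap <- sum(diff(recall) * (precision[-1] + precision[-length(precision)]) / 2)
  list(points = data.frame(recall = recall, precision = precision), ap = ap)
}

#' Intraclass correlation ICC(A,1)
#'
#' Single-measure, absolute-agreement, two-way random-effects intraclass
#' correlation (the McGraw-Wong A,1 form) with its F-based 95% confidence
#' interval, computed from the two-way ANOVA mean squares of an n-subjects
#' by k-raters matrix.
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns.
#' @param conf_level confidence level (default 0.95).
#' @return list with `icc`, `ci` (length 2) and the mean squares.
#' @export
icc_a1 <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3 || k < 2) stop("need at least 3 subjects and 2 raters", call. = FALSE)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((ratings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  # Satterthwaite CI (McGraw & Wong 1996)
  alpha <- 1 - conf_level
  fj <- msc / mse
  vn <- (k - 1) * (n - 1) * (k * icc * fj + n * (1 + (k - 1) * icc) - k * icc)^2
  vd <- (n - 1) * k^2 * icc^2 * fj^2 + (n * (1 + (k - 1) * icc) - k * icc)^2
  v <- vn / vd
  f_u <- stats::qf(1 - alpha / 2, n - 1, v)
  f_l <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_u * mse) /
    (f_u * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_l * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_l * msr)
  list(icc = icc, ci = c(lower, upper), msr = msr, msc = msc, mse = mse)
}

#' Agreement statistics for two paired timing series
#'
#' Compares two measurement series of the same quantity (e.g. EWT in
#' seconds from two raters): ICC(A,1) with its 95% CI, Bland-Altman bias
#' and 95% limits of agreement (bias +/- 1.96 sd of the paired differences,
#' direction `a - b`), Pearson r, and the Wilcoxon signed-rank test (exact
#' for n <= 25 after dropping zero differences, normal approximation with
#' continuity correction above).
#'
#' @param a,b equal-length numeric vectors (n >= 3), seconds.
#' @return list of class `agreement_report` with fields `n, icc, icc_ci,
#'   pearson_r, pearson_p, bias, loa_low, loa_high, wilcoxon_w, wilcoxon_p,
#'   flags`.
#' @export
agreement <- function(a, b) {
  if (length(a) != length(b)) stop("series differ in length", call. = FALSE)
  if (length(a) < 3) stop("need at least 3 paired measurements", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("missing values in timing series", call. = FALSE)
  flags <- character(0)
  d <- a - b
  bias <- mean(d)
  sd_d <- stats::sd(d)
  loa <- bias + c(-1, 1) * 1.96 * sd_d
  ic <- icc_a1(cbind(a, b))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    r <- NA_real_; r_p <- NA_real_
    flags <- c(flags, "pearson_undefined_zero_variance")
  } else {
    ct <- stats::cor.test(a, b)
    r <- unname(ct$estimate); r_p <- ct$p.value
  }
  if (all(d == 0)) {
    w <- 0; w_p <- NA_real_
    flags <- c(flags, "wilcoxon_all_differences_zero")
  } else {
    nz <- sum(d != 0)
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                              exact = nz <= 25,
                                              correct = TRUE))
    w <- unname(wt$statistic); w_p <- wt$p.value
  }
  structure(list(n = length(a), icc = ic$icc, icc_ci = ic$ci,
                 pearson_r = r, pearson_p = r_p,
                 bias = bias, loa_low = loa[1], loa_high = loa[2],
                 wilcoxon_w = w, wilcoxon_p = w_p, flags = flags),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement over %d paired measurements\n", x$n))
  cat(sprintf("  ICC(A,1) %.3f (95%% CI %.3f-%.3f)\n",
              x$icc, x$icc_ci[1], x$icc_ci[2]))
  cat(sprintf("  Pearson r %.3f (p = %.3g)\n", x$pearson_r, x$pearson_p))
  cat(sprintf("  Bland-Altman bias %.2f s (95%% LoA %.2f to %.2f)\n",
              x$bias, x$loa_low, x$loa_high))
  cat(sprintf("  Wilcoxon W = %.1f (p = %.3g)\n", x$wilcoxon_w, x$wilcoxon_p))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Per-class and weighted evaluation of predictions against truth
#'
#' One-vs-rest confusion counts per class, the scalar metric set, one-vs-
#' rest ROC AUC and AP using the class confidence as score (computed when
#' confidences are available and both classes are present), and the
#' sample-weighted averages across classes.
#'
#' @param pred data frame `frame_index,label,confidence` of predictions.
#' @param truth data frame `frame_index,label,...` of reference labels.
#' @param classes class vocabulary (default the three withdrawal classes).
#' @return list with `per_class` (data frame) and `weighted` (named list).
#' @export
evaluate_predictions <- function(pred, truth, classes = FRAME_LABELS) {
  m <- merge(pred, truth, by = "frame_index", suffixes = c("_pred", "_true"))
  if (nrow(m) == 0) stop("no overlapping frame indices", call. = FALSE)
  conf <- if ("confidence_pred" %in% names(m)) m$confidence_pred
  else if ("confidence" %in% names(m)) m$confidence else NULL
  per <- lapply(classes, function(cl) {
    is_p <- m$label_pred == cl
    is_t <- m$label_true == cl
    cc <- confusion_counts(tp = sum(is_p & is_t), tn = sum(!is_p & !is_t),
                           fp = sum(is_p & !is_t), fn = sum(!is_p & is_t))
    met <- class_metrics(cc)
    score <- if (!is.null(conf)) ifelse(is_p, conf, 1 - conf) else NULL
    auc <- ap <- NA_real_
    if (!is.null(score) && any(is_t) && !all(is_t)) {
      auc <- roc_auc(score, is_t)$auc
      ap <- pr_ap(score, is_t)$ap
    }
    data.frame(class = cl, n = sum(is_t),
               precision = met$precision, sensitivity = met$sensitivity,
               specificity = met$specificity, f1 = met$f1,
               accuracy = met$accuracy, ap = ap, auc = auc,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  w <- per$n
  weighted <- lapply(c("precision", "sensitivity", "specificity", "f1",
                       "accuracy", "ap", "auc"), function(col) {
    vals <- per[[col]]
    if (anyNA(vals)) NA_real_ else weighted_average(vals, w)
  })
  names(weighted) <- c("precision", "sensitivity", "specificity", "f1",
                       "accuracy", "ap", "auc")
  list(per_class = per, weighted = weighted)
}
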