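check_two_classes <- function(labels) {
  labels <- as.logical(labels)
  if (anyNA(labels)) abort("labels must be TRUE/FALSE without NA")
  if (!any(labels) || all(labels)) abort("need at least one positive and one negative")
  labels
}

#' ROC AUC
#'
#' Probability that a randomly chosen positive outscores a randomly chosen
#' negative, ties counted 1/2 (the Mann-Whitney identity, computed from
#' mid-ranks).
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical (TRUE = positive) or coercible.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- check_two_classes(labels)
  r <- rank(scores)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Precision-recall AUC
#'
#' Area under the precision-recall curve by step-wise summation over distinct
#' score thresholds (no linear interpolation between PR points): each block of
#' tied scores contributes its recall increment times the precision at that
#' threshold. With all scores equal the curve is the single point
#' (recall 1, precision = prevalence), so the area equals the prevalence.
#'
#' @inheritParams roc_auc
#' @return PR AUC in `(0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  labels <- check_two_classes(labels)
  ord <- order(-scores)
  s <- scores[ord]
  y <- labels[ord]
  n_pos <- sum(y)
  tp <- cumsum(y)
  fp <- cumsum(!y)
  block_end <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie block
  prec <- tp[block_end] / (tp[block_end] + fp[block_end])
  rec <- tp[block_end] / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Maximal Matthews correlation coefficient over thresholds
#'
#' Sweeps thresholds at every distinct score (predict positive when
#' `score >= t`), computes the MCC of each induced confusion matrix (zero
#' denominators give MCC 0), and returns the maximum with its threshold.
#'
#' @inheritParams roc_auc
#' @return one-row tibble (mcc, threshold).
#' @export
max_mcc <- function(scores, labels) {
  labels <- check_two_classes(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  best <- -Inf
  best_t <- NA_real_
  for (t in sort(unique(scores), decreasing = TRUE)) {
    pred <- scores >= t
    tp <- sum(pred & labels); fp <- sum(pred & !labels)
    fn <- n_pos - tp; tn <- n_neg - fp
    den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
    mcc <- if (den == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / den
    if (mcc > best) { best <- mcc; best_t <- t }
  }
  tibble(mcc = best, threshold = best_t)
}

#' Mann-Whitney U test
#'
#' Exact p-value by enumeration when `n_x * n_y <= 400` and there are no
#' ties, otherwise the normal approximation with tie and continuity
#' correction (both via [stats::wilcox.test()]). U counts pairs where x
#' outranks y.
#'
#' @param x,y numeric score vectors (non-empty).
#' @param alternative `"two_sided"`, `"less"` (x tends smaller) or
#'   `"greater"`.
#' @return one-row tibble (U, p_value, exact).
#' @export
mann_whitney <- function(x, y, alternative = c("two_sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) abort("empty input")
  alt <- sub("_", ".", alternative)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- length(x) * length(y) <= 400 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alt, exact = exact,
                       correct = TRUE)
  )
  tibble(U = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}
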