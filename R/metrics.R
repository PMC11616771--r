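#' Area under the precision-recall curve (average precision)
#'
#' AUPRC is computed as average precision with step interpolation:
#' sum over decreasing score thresholds of precision times the increment
#' in recall. Ties in scores are handled by thresholding on unique score
#' values (tied examples enter together).
#'
#' @param labels binary vector (1 = positive).
#' @param scores numeric scores, higher = more positive.
#' @return scalar in \[0, 1\].
#' @export
auprc <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% 0:1))
  n_pos <- sum(labels == 1)
  if (n_pos == 0 || n_pos == length(labels)) {
    stop("both classes must be present")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # cut at the last index of each unique score value
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(prec * diff(c(0, rec)))
}

#' Area under the ROC curve
#'
#' Computed via the Mann-Whitney statistic: the fraction of
#' (positive, negative) pairs ranked concordantly, counting ties as 1/2
#' (midrank formula).
#'
#' @inheritParams auprc
#' @return scalar in \[0, 1\].
#' @export
auroc <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% 0:1))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Paired Wilcoxon signed-rank comparison of per-run metrics
#'
#' Two-sided signed-rank test on paired metric values (one per evaluation
#' run), with zero differences dropped per the standard convention. When
#' every difference is zero the test is uninformative and p = 1 is
#' returned with a warning.
#'
#' @param metric_a,metric_b equal-length (>= 5) numeric vectors, paired by
#'   run.
#' @return two-sided p-value.
#' @export
compare_wilcoxon <- function(metric_a, metric_b) {
  stopifnot(length(metric_a) == length(metric_b), length(metric_a) >= 5)
  d <- metric_a - metric_b
  if (all(d == 0)) {
    warning("all paired differences are zero; test is uninformative")
    return(1)
  }
  stats::wilcox.test(metric_a, metric_b, paired = TRUE,
                     alternative = "two.sided")$p.value
}
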