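#' Area under the ROC curve (tie-adjusted concordance)
#'
#' AUROC is computed as the pairwise concordance probability: over all
#' (positive, negative) pairs, the fraction in which the positive scores
#' higher, counting ties as 1/2. This equals the trapezoidal area under
#' the ROC curve built over all distinct score thresholds and handles tied
#' scores exactly.
#'
#' @param scores Numeric risk scores (higher = more positive-like).
#' @param labels 0/1 labels (1 = positive class).
#' @return AUROC in [0, 1].
#' @examples
#' auroc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("undefined metric: AUROC requires both classes")
  }
  r <- rank(scores)  # midranks handle ties as 1/2 credit
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ROC/PR staircase over distinct thresholds (descending); internal.
curve_points <- function(scores, labels) {
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # cumulative counts at each position, collapsed to distinct thresholds
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  last <- c(s[-1] != s[-length(s)], TRUE)  # last row of each tied block
  thr <- s[last]; tp <- tp[last]; fp <- fp[last]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  data.frame(
    threshold = thr,
    tpr = if (n1 > 0) tp / n1 else NA_real_,
    fpr = if (n0 > 0) fp / n0 else NA_real_,
    precision = ifelse(tp + fp > 0, tp / (tp + fp), NA_real_),
    recall = if (n1 > 0) tp / n1 else NA_real_,
    tp = tp, fp = fp, fn = n1 - tp, tn = n0 - fp
  )
}

#' Area under the precision-recall curve (step interpolation)
#'
#' The precision-recall staircase is built over distinct score thresholds
#' (descending) and integrated with right-continuous step interpolation:
#' sum over thresholds of (recall increment) x (precision at that
#' threshold). Step interpolation avoids the optimistic bias of linear
#' interpolation in PR space.
#'
#' @inheritParams auroc
#' @return AUPRC in (0, 1].
#' @examples
#' auprc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (sum(labels == 1) == 0) {
    stop("undefined metric: AUPRC requires at least one positive")
  }
  cp <- curve_points(scores, labels)
  d_recall <- diff(c(0, cp$recall))
  sum(d_recall * cp$precision)
}

#' Optimal cut-point by Youden's J
#'
#' Scans the observed score thresholds (classify positive when
#' score >= threshold) and maximizes J = sensitivity + specificity - 1;
#' ties are resolved toward the lower threshold.
#'
#' @inheritParams auroc
#' @return List with \code{threshold}, \code{sensitivity},
#'   \code{specificity}, \code{j}.
#' @export
youden_cutpoint <- function(scores, labels) {
  labels <- as.integer(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0) {
    stop("undefined metric: cut-point requires both classes")
  }
  cp <- curve_points(scores, labels)
  j <- cp$tpr - cp$fpr
  best <- which(j == max(j))
  best <- best[which.min(cp$threshold[best])]
  list(threshold = cp$threshold[best],
       sensitivity = cp$tpr[best],
       specificity = 1 - cp$fpr[best],
       j = j[best])
}

#' Mann-Whitney U test (normal approximation)
#'
#' U from rank sums with midranks for ties; the two-sided P-value uses the
#' normal approximation with tie-corrected variance and continuity
#' correction (no exact small-sample path). U is reported for the first
#' sample, i.e. the number of (a, b) pairs with a > b, ties counting 1/2.
#'
#' @param a,b Numeric samples (non-empty).
#' @return List with \code{u} and \code{p} (two-sided).
#' @examples
#' mann_whitney_u(rnorm(20), rnorm(20, 1))
#' @export
mann_whitney_u <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) {
    stop("both samples must be non-empty")
  }
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
  list(u = unname(wt$statistic), p = wt$p.value)
}

#' Pearson chi-squared test on a contingency table
#'
#' Pearson statistic without continuity correction; P from the chi-squared
#' distribution with (r - 1)(k - 1) degrees of freedom.
#'
#' @param tab Matrix of non-negative counts with all row and column
#'   margins positive.
#' @return List with \code{statistic}, \code{p}, \code{df}.
#' @examples
#' chi_squared(matrix(c(20, 5, 10, 15), 2))
#' @export
chi_squared <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("all table margins must be positive")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p = ct$p.value,
       df = unname(ct$parameter))
}
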