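#' ROC analysis
#'
#' Builds the full ROC curve over all distinct score thresholds (predict
#' positive when `score >= threshold`) and computes the AUC by the
#' rank/Mann-Whitney identity, in which tied score pairs count one half.
#' The trapezoidal area under the returned curve equals the rank AUC to
#' machine precision.
#'
#' The positive class is tumor progression (label 1) throughout, so
#' sensitivity is the progression-detection rate.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels binary labels (1 = positive).
#' @return An object of class `roc_result`: `auc`, and `curve`, a
#'   data.frame with `threshold`, `fpr`, `tpr`, `sens`, `spec` (one row
#'   per distinct threshold plus the two trivial corners).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  auc <- auc_rank(scores, labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & labels == 1L), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & labels == 0L), numeric(1))
  curve <- data.frame(threshold = c(Inf, thr),
                      fpr = c(0, fp / n0),
                      tpr = c(0, tp / n1))
  curve$sens <- curve$tpr
  curve$spec <- 1 - curve$fpr
  structure(list(auc = auc, curve = curve, n_pos = n1, n_neg = n0),
            class = "roc_result")
}

# AUC via the rank (Mann-Whitney) identity; midranks give ties weight 1/2.
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Optimal decision cutoff
#'
#' The cutoff at which the product of sensitivity and specificity is
#' maximal; among ties the cutoff with the higher specificity wins
#' (conservative toward not over-calling progression).  When every score
#' is identical the product is maximized at a degenerate corner, which is
#' returned with `degenerate = TRUE`.
#'
#' @param roc a [roc_auc()] result.
#' @return List with `cutoff`, `sensitivity`, `specificity`,
#'   `degenerate`.
#' @export
optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  cv <- roc$curve
  prod <- cv$sens * cv$spec
  best <- which(prod == max(prod))
  if (length(best) > 1L) best <- best[which.max(cv$spec[best])]
  list(cutoff = cv$threshold[best],
       sensitivity = cv$sens[best],
       specificity = cv$spec[best],
       degenerate = max(prod) == 0)
}

#' Confidence interval for the AUC
#'
#' DeLong's variance estimate by default: the AUC is an average of
#' placement values, whose empirical variances over positives and
#' negatives give `var(AUC) = var(V10)/n1 + var(V01)/n0`; the interval is
#' the normal one, clipped to [0, 1].  A seeded stratified-bootstrap
#' percentile interval is available as an alternative and is used as a
#' fallback (with a warning) when the observed AUC is degenerate (0 or 1),
#' where the DeLong variance collapses.
#'
#' @param scores,labels as in [roc_auc()].
#' @param level confidence level; default 0.95.
#' @param method `"delong"` (default) or `"bootstrap"`.
#' @param n_boot bootstrap replicates; default 2000.
#' @param seed bootstrap seed.
#' @return List with `low`, `high`, `method`.
#' @export
auc_ci <- function(scores, labels, level = 0.95,
                   method = c("delong", "bootstrap"),
                   n_boot = 2000L, seed = 1L) {
  method <- match.arg(method)
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 < 2L || n0 < 2L) stop("need at least 2 members per class")
  auc <- auc_rank(scores, labels)
  if (method == "delong" && (auc == 0 || auc == 1)) {
    warning("degenerate AUC; falling back to the bootstrap interval")
    method <- "bootstrap"
  }
  if (method == "delong") {
    xs <- scores[labels == 1L]
    ys <- scores[labels == 0L]
    # placement values
    v10 <- vapply(xs, function(x) mean((x > ys) + 0.5 * (x == ys)),
                  numeric(1))
    v01 <- vapply(ys, function(y) mean((xs > y) + 0.5 * (xs == y)),
                  numeric(1))
    v <- stats::var(v10) / n1 + stats::var(v01) / n0
    z <- stats::qnorm(1 - (1 - level) / 2)
    lo <- max(0, auc - z * sqrt(v))
    hi <- min(1, auc + z * sqrt(v))
  } else {
    set.seed(as.integer(seed))
    pos <- which(labels == 1L); neg <- which(labels == 0L)
    reps <- vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(pos, n1, replace = TRUE),
               sample(neg, n0, replace = TRUE))
      auc_rank(scores[idx], labels[idx])
    }, numeric(1))
    qs <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE, type = 7)
    lo <- qs[1]; hi <- qs[2]
  }
  list(low = lo, high = hi, method = method)
}

#' Mann-Whitney U test
#'
#' Two-sided intergroup comparison.  Exact enumeration is used for small
#' samples without ties (total n <= 20); otherwise the tie-corrected
#' normal approximation.  `U` is reported from the side of group `a`.
#'
#' @param a,b numeric samples.
#' @return List with `U` and `p`.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  has_ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- (length(a) + length(b)) <= 20L && !has_ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (use_exact) "exact" else "normal_approx")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value obtained by summing the probabilities of all tables
#' (with the observed margins) that are no more probable than the observed
#' one.  A zero margin leaves nothing to test: p = 1 with a warning.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L)) stop("`tab` must be 2x2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("cells must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin: nothing to test, p = 1")
    return(1)
  }
  stats::fisher.test(tab)$p.value
}
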