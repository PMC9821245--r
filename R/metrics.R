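#' Cross-tabulate predictions against labels
#'
#' @param pred logical predictions (`TRUE` = fissure)
#' @param truth logical labels
#' @return a [ConfusionTable-class]
#' @examples
#' ct <- confusionTable(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' ct
#' @export
confusionTable <- function(pred, truth) {
  stopifnot2(length(pred) == length(truth), "pred/truth length mismatch")
  pred <- as.logical(pred); truth <- as.logical(truth)
  new("ConfusionTable",
      tp = sum(pred & truth), fp = sum(pred & !truth),
      fn = sum(!pred & truth), tn = sum(!pred & !truth))
}

#' Diagnostic test statistics from a confusion table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy, positive
#' likelihood ratio `sens/(1-spec)` (flagged infinite at perfect
#' specificity) and negative likelihood ratio `(1-sens)/spec`.
#'
#' @param ct a [ConfusionTable-class]
#' @return list with `sensitivity`, `specificity`, `accuracy` (fractions),
#'   `plr`, `nlr` and `plrInfinite`
#' @examples
#' ct <- new("ConfusionTable", tp = 94L, fp = 1L, fn = 0L, tn = 28L)
#' diagnosticMetrics(ct)$specificity  # 28/29
#' @export
diagnosticMetrics <- function(ct) {
  stopifnot2(ct@tp + ct@fn > 0 && ct@tn + ct@fp > 0,
             "both classes must be present")
  sens <- ct@tp / (ct@tp + ct@fn)
  spec <- ct@tn / (ct@tn + ct@fp)
  acc <- (ct@tp + ct@tn) / (ct@tp + ct@fp + ct@fn + ct@tn)
  plrInf <- spec == 1
  list(sensitivity = sens, specificity = spec, accuracy = acc,
       plr = if (plrInf) Inf else sens / (1 - spec),
       nlr = (1 - sens) / spec, plrInfinite = plrInf)
}

#' ROC curve and area under the curve
#'
#' Threshold sweep over the unique scores with trapezoidal integration
#' (delegated to \pkg{pROC}); tied scores enter simultaneously.
#'
#' @param probs numeric scores (higher = more fissure-like)
#' @param labels logical labels
#' @return list with `auc` and `points` (threshold, sensitivity,
#'   specificity)
#' @export
rocAuc <- function(probs, labels) {
  labels <- as.logical(labels)
  stopifnot2(any(labels) && any(!labels), "both classes must be present")
  r <- pROC::roc(response = labels, predictor = probs,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  pts <- pROC::coords(r, x = "all", ret = c("threshold", "sensitivity",
                                            "specificity"),
                      transpose = FALSE)
  list(auc = as.numeric(pROC::auc(r)), points = as.data.frame(pts))
}

#' Mid-p McNemar test on discordant pairs
#'
#' Exact paired comparison of two classifiers on the same discs: with `b`
#' and `c` the discordant counts, `n = b + c` and `k = min(b, c)`, the
#' mid-p-value is `2 P(K <= k) - P(K = k)` for `K ~ Binomial(n, 1/2)`,
#' clipped to [0, 1]. Half of the point probability is removed from the
#' usual exact two-sided p-value, which reduces the conservatism of the
#' exact test for paired proportions.
#'
#' @param b,c discordant counts (classifier A wrong/B right, and vice
#'   versa)
#' @return list with `b`, `c` and `pMid`; `pMid` is `NA` when `b = c = 0`
#'   (no discordance)
#' @examples
#' mcnemarMidP(5, 0)$pMid  # 0.03125
#' @export
mcnemarMidP <- function(b, c) {
  stopifnot2(b >= 0 && c >= 0, "counts must be non-negative")
  if (b + c == 0)
    return(list(b = b, c = c, pMid = NA_real_))
  n <- b + c
  k <- min(b, c)
  p <- 2 * pbinom(k, n, 0.5) - dbinom(k, n, 0.5)
  list(b = b, c = c, pMid = min(max(p, 0), 1))
}

#' Format diagnostic metrics the way reports print them
#'
#' Percentages to one decimal, likelihood ratios to three decimals.
#'
#' @param dm a [diagnosticMetrics()] result
#' @return named numeric: `sensitivity`, `specificity`, `accuracy` (as
#'   percentages), `plr`, `nlr`
#' @export
reportMetrics <- function(dm) {
  c(sensitivity = asPercent(dm$sensitivity),
    specificity = asPercent(dm$specificity),
    accuracy = asPercent(dm$accuracy),
    plr = if (dm$plrInfinite) Inf else round(dm$plr, 3),
    nlr = round(dm$nlr, 3))
}
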