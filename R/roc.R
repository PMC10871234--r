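#' ROC curve and AUC
#'
#' The AUC is computed as the Mann-Whitney concordance probability — the
#' chance a random event scores above a random non-event, with ties counted
#' half — which is identical to the trapezoidal area under the empirical ROC
#' curve.
#'
#' @param probabilities Numeric scores (higher = more event-like).
#' @param labels Logical or 0/1 event indicator.
#' @return List of class `roc_result`: `auc` and a `curve` tibble
#'   (`threshold`, `fpr`, `tpr`).
#' @examples
#' roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0))$auc  # 1
#' @export
roc_auc <- function(probabilities, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(probabilities) & !is.na(labels)
  p <- probabilities[ok]; y <- labels[ok]
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  r <- rank(p, ties.method = "average")
  auc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thr <- c(Inf, sort(unique(p), decreasing = TRUE))
  curve <- tibble::tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(p[y] >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(p[!y] >= t), numeric(1))
  )
  structure(list(auc = auc, curve = curve), class = "roc_result")
}

#' Area under the precision-recall curve
#'
#' Average-precision estimator: the sum over events, in decreasing score
#' order, of precision at each recall step.
#'
#' @inheritParams roc_auc
#' @return AUC-PR as a single number.
#' @export
pr_auc <- function(probabilities, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(probabilities) & !is.na(labels)
  p <- probabilities[ok]; y <- labels[ok]
  if (sum(y) == 0 || sum(!y) == 0) abort("both classes must be present")
  o <- order(p, decreasing = TRUE)
  y <- y[o]
  cum_tp <- cumsum(y)
  precision <- cum_tp / seq_along(y)
  sum(precision[y]) / sum(y)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d thresholds)\n",
              x$auc, nrow(x$curve)))
  invisible(x)
}
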