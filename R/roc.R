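# ROC analysis of patient-level scores: AUC, Youden index and associated
# criterion, prevalence-aware operating metrics.

#' ROC curve of patient scores
#'
#' Thresholds are the midpoints between adjacent distinct score values
#' plus -Inf/+Inf sentinels; a case is called positive when its score is
#' at or above the threshold. The AUC is the trapezoidal integral of the
#' curve, which on the same data equals the rank statistic
#' `P(score_pos > score_neg) + 0.5 P(tie)`.
#'
#' @param data Data frame of scores (e.g. the `scores` element of an
#'   [cross_validate()] result).
#' @param truth Column with the true class (two classes present).
#' @param score Numeric score column (larger = more positive).
#' @param positive Value of `truth` counted as positive; defaults to the
#'   last factor level (the "impaired" convention of this package).
#' @return An `hw_roc`: `curve` (threshold, sensitivity, specificity),
#'   `auc`, `youden_j`, `criterion`, `operating` (metrics at the
#'   criterion under the sample's class prevalence), `n_pos`, `n_neg`.
#' @export
roc_curve <- function(data, truth, score, positive = NULL) {
  tr <- dplyr::pull(data, {{ truth }})
  sc <- dplyr::pull(data, {{ score }})
  stopifnot(is.numeric(sc))
  lev <- if (is.factor(tr)) levels(droplevels(tr)) else sort(unique(as.character(tr)))
  if (length(lev) != 2)
    stop_config("truth must contain exactly two classes")
  positive <- positive %||% lev[[length(lev)]]
  if (!positive %in% lev) stop_config("positive class not present in truth")
  is_pos <- as.character(tr) == positive

  s <- sort(unique(sc))
  thresholds <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  sens <- vapply(thresholds, function(t) mean(sc[is_pos] >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(sc[!is_pos] < t), numeric(1))
  curve <- tibble::tibble(threshold = thresholds,
                          sensitivity = sens, specificity = spec)

  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)

  j <- sens + spec - 1
  best <- which.max(j)  # thresholds ascend: first max = lowest criterion
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  op <- operating_metrics(sens[best], spec[best], n_pos, n_neg)

  structure(list(curve = curve, auc = auc, youden_j = j[best],
                 criterion = thresholds[best], operating = op,
                 n_pos = n_pos, n_neg = n_neg, positive = positive),
            class = "hw_roc")
}

#' @export
print.hw_roc <- function(x, ...) {
  cat(sprintf(
    "<hw_roc> positive = %s (%d vs %d)\n  AUC %.3f | Youden J %.3f at criterion %.3f | sens %.3f spec %.3f\n  acc %.3f ppv %.3f npv %.3f\n",
    x$positive, x$n_pos, x$n_neg, x$auc, x$youden_j, x$criterion,
    x$operating$sensitivity, x$operating$specificity,
    x$operating$accuracy, x$operating$ppv, x$operating$npv))
  invisible(x)
}

#' Youden index and associated criterion
#'
#' `J = max(sensitivity + specificity - 1)` over all thresholds; ties are
#' broken towards the lower threshold (higher sensitivity).
#'
#' @param roc An `hw_roc` from [roc_curve()].
#' @return One-row tibble: `youden_j`, `criterion`.
#' @export
youden <- function(roc) {
  stopifnot(inherits(roc, "hw_roc"))
  j <- roc$curve$sensitivity + roc$curve$specificity - 1
  best <- which.max(j)
  tibble::tibble(youden_j = j[best], criterion = roc$curve$threshold[best])
}

#' Prevalence-aware operating metrics
#'
#' Predictive values and accuracy at an operating point, under the class
#' prevalence implied by the cohort sizes:
#' `accuracy = (sens * n_pos + spec * n_neg) / (n_pos + n_neg)`,
#' `ppv = sens * n_pos / (sens * n_pos + (1 - spec) * n_neg)`,
#' `npv = spec * n_neg / (spec * n_neg + (1 - sens) * n_pos)`. A zero
#' denominator yields `NA` (undefined, not an error).
#'
#' @param sensitivity,specificity Proportions in \[0, 1\].
#' @param n_pos,n_neg Positive/negative cohort sizes (>= 1).
#' @return One-row tibble: sensitivity, specificity, ppv, npv, accuracy,
#'   youden_j, n_pos, n_neg.
#' @export
operating_metrics <- function(sensitivity, specificity, n_pos, n_neg) {
  if (sensitivity < 0 || sensitivity > 1 || specificity < 0 || specificity > 1)
    stop_config("sensitivity and specificity must lie in [0, 1]")
  if (n_pos < 1 || n_neg < 1) stop_config("n_pos and n_neg must be >= 1")
  tp <- sensitivity * n_pos
  tn <- specificity * n_neg
  fp <- (1 - specificity) * n_neg
  fn <- (1 - sensitivity) * n_pos
  safe_div <- function(a, b) if (b <= 0) NA_real_ else a / b
  tibble::tibble(
    sensitivity = sensitivity, specificity = specificity,
    ppv = safe_div(tp, tp + fp), npv = safe_div(tn, tn + fn),
    accuracy = (tp + tn) / (n_pos + n_neg),
    youden_j = sensitivity + specificity - 1,
    n_pos = n_pos, n_neg = n_neg
  )
}
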