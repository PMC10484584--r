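#' ROC and precision-recall curves with trapezoidal AUCs
#'
#' Operating points are generated at every distinct score (decision rule:
#' positive if score >= threshold), plus the all-positive and all-negative
#' endpoints. Used to assess how well one index (e.g. the autonomic arousal
#' index) detects a binary condition (e.g. cortical ArI >= 20).
#'
#' @param scores Numeric vector of scores (higher = more likely positive).
#' @param labels Logical/0-1 vector of true conditions.
#' @return A list with tibbles `roc` (threshold, fpr, tpr) and `pr`
#'   (threshold, recall, precision) and scalars `auc_roc`, `auc_pr`.
#' @export
roc_pr_curves <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")

  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- vapply(thr, function(t) {
    pred <- scores >= t
    c(tp = sum(pred & labels), fp = sum(pred & !labels))
  }, numeric(2))
  tp <- c(0, pts["tp", ])
  fp <- c(0, pts["fp", ])
  thr_full <- c(Inf, thr)

  tpr <- tp / n_pos
  fpr <- fp / n_neg
  roc <- tibble::tibble(threshold = thr_full, fpr = fpr, tpr = tpr)
  auc_roc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)

  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 1)
  rec <- tpr
  pr <- tibble::tibble(threshold = thr_full, recall = rec, precision = prec)
  auc_pr <- sum(diff(rec) * (utils::head(prec, -1) + utils::tail(prec, -1)) / 2)

  list(roc = roc, pr = pr, auc_roc = auc_roc, auc_pr = auc_pr)
}

#' Plot ROC and precision-recall curves
#'
#' @param curves Result of [roc_pr_curves()].
#' @param which `"roc"` or `"pr"`.
#' @return A ggplot object.
#' @export
plot_curves <- function(curves, which = c("roc", "pr")) {
  which <- match.arg(which)
  if (which == "roc") {
    ggplot2::ggplot(curves$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_step() +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "False positive rate", y = "True positive rate",
                    subtitle = sprintf("AUC = %.3f", curves$auc_roc)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(curves$pr,
                    ggplot2::aes(x = .data$recall, y = .data$precision)) +
      ggplot2::geom_step() +
      ggplot2::labs(x = "Recall", y = "Precision",
                    subtitle = sprintf("AUC = %.3f", curves$auc_pr)) +
      ggplot2::theme_minimal()
  }
}
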