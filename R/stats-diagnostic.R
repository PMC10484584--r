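SEVERITY_LEVELS <- c("None", "Mild", "Moderate", "Severe")

#' Build a 4x4 severity confusion matrix
#'
#' Rows are the predicted class, columns the true class, both over
#' None/Mild/Moderate/Severe.
#'
#' @param predicted,true Vectors of severity classes (character or factor
#'   with the levels None, Mild, Moderate, Severe).
#' @return An integer 4x4 matrix with dimnames `predicted` x `true`.
#' @export
confusion4 <- function(predicted, true) {
  p <- factor(as.character(predicted), levels = SEVERITY_LEVELS)
  t <- factor(as.character(true), levels = SEVERITY_LEVELS)
  if (anyNA(p) || anyNA(t)) stop("unknown severity class label")
  m <- table(predicted = p, true = t)
  matrix(as.integer(m), 4, 4, dimnames = list(predicted = SEVERITY_LEVELS,
                                              true = SEVERITY_LEVELS))
}

as_confusion4 <- function(cm) {
  cm <- as.matrix(cm)
  if (!all(dim(cm) == c(4, 4))) stop("confusion matrix must be 4x4")
  if (any(cm < 0) || any(cm != round(cm))) stop("counts must be non-negative integers")
  dimnames(cm) <- list(predicted = SEVERITY_LEVELS, true = SEVERITY_LEVELS)
  cm
}

#' Wilson score interval with continuity correction
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param level Confidence level, default 0.95.
#' @return Numeric vector `c(lo, hi)`, clipped to `[0, 1]`.
#' @export
wilson_ci <- function(k, n, level = 0.95) {
  stopifnot(n > 0, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  lo <- if (k == 0) 0 else {
    (2 * n * p + z^2 - 1 -
       z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * (1 - p) + 1))) / (2 * (n + z^2))
  }
  hi <- if (k == n) 1 else {
    (2 * n * p + z^2 + 1 +
       z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * (1 - p) - 1))) / (2 * (n + z^2))
  }
  c(max(0, lo), min(1, hi))
}

#' Simel log-method confidence intervals for likelihood ratios
#'
#' `LR+ = sens/(1-spec)` and `LR- = (1-sens)/spec`, with CIs computed on the
#' log scale: `exp(log(LR) +/- z * SE)` where
#' `SE^2(log LR+) = (1-sens)/(n_pos*sens) + spec/(n_neg*(1-spec))` and
#' `SE^2(log LR-) = sens/(n_pos*(1-sens)) + (1-spec)/(n_neg*spec)`.
#' Degenerate cells (sens or spec equal to 0 or 1) give a point estimate of
#' 0 or Inf with the corresponding open bound reported as `NA`.
#'
#' @param sens,spec Sensitivity and specificity (proportions).
#' @param n_pos,n_neg Numbers of true positives-class and negatives-class
#'   subjects (the denominators of sens and spec).
#' @param level Confidence level.
#' @return Tibble with rows `lr_pos`, `lr_neg` and columns `estimate`,
#'   `conf_low`, `conf_high`.
#' @export
lr_ci <- function(sens, spec, n_pos, n_neg, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  lrp <- sens / (1 - spec)
  lrn <- (1 - sens) / spec
  lr_one <- function(lr, se2) {
    if (!is.finite(lr) || lr == 0 || !is.finite(se2)) {
      # open interval: a zero LR has a closed lower bound at 0, an infinite
      # LR a closed upper bound at Inf; the other side is unbounded (NA)
      if (lr == 0) c(0, NA_real_) else c(NA_real_, Inf)
    } else {
      exp(log(lr) + c(-1, 1) * z * sqrt(se2))
    }
  }
  se2_p <- (1 - sens) / (n_pos * sens) + spec / (n_neg * (1 - spec))
  se2_n <- sens / (n_pos * (1 - sens)) + (1 - spec) / (n_neg * spec)
  cip <- lr_one(lrp, se2_p)
  cin <- lr_one(lrn, se2_n)
  tibble::tibble(
    quantity = c("lr_pos", "lr_neg"),
    estimate = c(lrp, lrn),
    conf_low = c(cip[1], cin[1]),
    conf_high = c(cip[2], cin[2])
  )
}

#' Cohen's kappa with Cohen's 1960 confidence interval
#'
#' For a square confusion matrix of counts, `kappa = (p_o - p_e)/(1 - p_e)`
#' with `p_e` from the row/column marginals. The CI uses Cohen's approximate
#' standard error `sqrt(p_o (1 - p_o) / (n (1 - p_e)^2))`.
#'
#' @param cm Square matrix of counts (rows predicted, columns true).
#' @param level Confidence level.
#' @return One-row tibble with `kappa`, `conf_low`, `conf_high`, `n`.
#' @export
cohen_kappa <- function(cm, level = 0.95) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("cohen_kappa() needs a square matrix")
  n <- sum(cm)
  if (n <= 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe >= 1) stop("chance agreement is 1; kappa undefined")
  kap <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  z <- stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(kappa = kap, conf_low = kap - z * se,
                 conf_high = kap + z * se, n = n)
}

# Collapse a 4x4 severity confusion matrix to 2x2 at an AHI cut (5, 15, 30).
# Positive class = severity at or above the cut.
binarize_confusion <- function(cm, cut) {
  cm <- as_confusion4(cm)
  cut_idx <- match(cut, c(5, 15, 30))
  if (is.na(cut_idx)) stop("cut must be one of 5, 15, 30")
  pos <- seq(cut_idx + 1, 4)           # classes counted as positive
  neg <- seq_len(cut_idx)
  tp <- sum(cm[pos, pos, drop = FALSE])
  fn <- sum(cm[neg, pos, drop = FALSE])
  fp <- sum(cm[pos, neg, drop = FALSE])
  tn <- sum(cm[neg, neg, drop = FALSE])
  matrix(c(tp, fn, fp, tn), 2, 2,
         dimnames = list(predicted = c("pos", "neg"), true = c("pos", "neg")))
}

#' Binary diagnostic metrics at an AHI severity cut
#'
#' Collapses a 4x4 severity confusion matrix at one diagnostic AHI threshold
#' (5, 15 or 30 events/h) and computes prevalence, accuracy, sensitivity and
#' specificity (Wilson continuity-corrected CIs), positive/negative
#' likelihood ratios (Simel log-method CIs) and Cohen's kappa (Cohen-1960
#' CI).
#'
#' @param cm 4x4 confusion matrix, rows predicted, columns true.
#' @param cut AHI threshold in events/h: 5, 15 or 30.
#' @param level Confidence level.
#' @return Tibble with columns `metric`, `estimate`, `conf_low`, `conf_high`.
#' @export
binary_metrics <- function(cm, cut, level = 0.95) {
  b <- binarize_confusion(cm, cut)
  tp <- b["pos", "pos"]; fn <- b["neg", "pos"]
  fp <- b["pos", "neg"]; tn <- b["neg", "neg"]
  n <- tp + fn + fp + tn
  n_pos <- tp + fn
  n_neg <- fp + tn
  if (n_pos == 0 || n_neg == 0) {
    stop("one class is empty after binarization; metrics undefined")
  }
  sens <- tp / n_pos
  spec <- tn / n_neg
  acc_ci <- wilson_ci(tp + tn, n, level)
  sens_ci <- wilson_ci(tp, n_pos, level)
  spec_ci <- wilson_ci(tn, n_neg, level)
  lrs <- lr_ci(sens, spec, n_pos, n_neg, level)
  kap <- cohen_kappa(b, level)
  tibble::tibble(
    metric = c("prevalence", "accuracy", "sensitivity", "specificity",
               "lr_pos", "lr_neg", "kappa"),
    estimate = c(n_pos / n, (tp + tn) / n, sens, spec,
                 lrs$estimate, kap$kappa),
    conf_low = c(NA, acc_ci[1], sens_ci[1], spec_ci[1],
                 lrs$conf_low, kap$conf_low),
    conf_high = c(NA, acc_ci[2], sens_ci[2], spec_ci[2],
                  lrs$conf_high, kap$conf_high)
  )
}

#' Four-class severity classification metrics
#'
#' With rows = predicted and columns = true, cells above the diagonal hold
#' subjects whose severity was underestimated (true class exceeds predicted)
#' and cells below the diagonal those overestimated.
#'
#' @param cm 4x4 confusion matrix.
#' @param level Confidence level.
#' @return Tibble with rows `accuracy`, `underestimated`, `overestimated`,
#'   `kappa`, `off_by_more_than_one` and columns `estimate`, `conf_low`,
#'   `conf_high`, `count`.
#' @export
fourclass_metrics <- function(cm, level = 0.95) {
  cm <- as_confusion4(cm)
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  correct <- sum(diag(cm))
  under <- sum(cm[upper.tri(cm)])
  over <- sum(cm[lower.tri(cm)])
  idx <- abs(row(cm) - col(cm)) >= 2
  off2 <- sum(cm[idx])
  kap <- cohen_kappa(cm, level)
  ci_acc <- wilson_ci(correct, n, level)
  ci_und <- wilson_ci(under, n, level)
  ci_ove <- wilson_ci(over, n, level)
  tibble::tibble(
    metric = c("accuracy", "underestimated", "overestimated", "kappa",
               "off_by_more_than_one"),
    estimate = c(correct / n, under / n, over / n, kap$kappa, off2),
    conf_low = c(ci_acc[1], ci_und[1], ci_ove[1], kap$conf_low, NA),
    conf_high = c(ci_acc[2], ci_und[2], ci_ove[2], kap$conf_high, NA),
    count = c(correct, under, over, NA, off2)
  )
}
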