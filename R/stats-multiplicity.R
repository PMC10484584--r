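#' Benjamini-Yekutieli false-discovery-rate control
#'
#' Controls the FDR of a family of m tests under arbitrary dependence.
#' Sorted p-values `p(k)` are compared to `k * alpha / (m * c(m))` with
#' `c(m) = sum(1/i, i = 1..m)`; the critical threshold is the comparison
#' value at the largest admissible `k` (or `alpha / (m * c(m))` when no test
#' is rejected), and a test is significant iff its p-value is at or below
#' the threshold.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param alpha Target false discovery rate, default 0.05.
#' @return A list with `threshold`, `n_rejected`, and a tibble `tests`
#'   (`p`, `rank`, `critical`, `significant`), in input order.
#' @export
benjamini_yekutieli <- function(pvals, alpha = 0.05) {
  stopifnot(length(pvals) >= 1, all(pvals >= 0 & pvals <= 1))
  m <- length(pvals)
  cm <- sum(1 / seq_len(m))
  ord <- order(pvals)
  ps <- pvals[ord]
  crit <- seq_len(m) * alpha / (m * cm)
  admissible <- which(ps <= crit)
  if (length(admissible) == 0) {
    threshold <- alpha / (m * cm)
    k_star <- 0L
  } else {
    k_star <- max(admissible)
    threshold <- crit[k_star]
  }
  rank_in <- integer(m)
  rank_in[ord] <- seq_len(m)
  list(
    threshold = threshold,
    n_rejected = k_star,
    tests = tibble::tibble(
      p = pvals,
      rank = rank_in,
      critical = crit[rank_in],
      significant = pvals <= threshold
    )
  )
}

#' Paired comparison of a diagnostic metric between two methods
#'
#' For paired proportions (e.g. per-subject correctness under two scoring
#' methods) an exact McNemar test on the discordant pairs is used. For
#' derived statistics without a per-subject decomposition (Cohen's kappa,
#' likelihood ratios) a seeded subject-level bootstrap compares the two
#' methods: subjects are resampled with replacement, the statistic difference
#' is recomputed, and a two-sided p-value is obtained from the bootstrap
#' distribution's tail mass around zero.
#'
#' @param a,b For `kind = "proportion"`: logical vectors (per-subject
#'   success under each method). For `kind = "kappa"`: integer class vectors
#'   `list(pred, true)` per method is not needed - supply `a`, `b` as
#'   data frames with columns `pred` and `true` (one row per subject).
#' @param kind `"proportion"` or `"kappa"`.
#' @param n_boot Bootstrap resamples (kappa), default 10000.
#' @param seed RNG seed for the bootstrap.
#' @return The two-sided p-value.
#' @export
compare_paired <- function(a, b, kind = c("proportion", "kappa"),
                           n_boot = 10000, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "proportion") {
    a <- as.logical(a); b <- as.logical(b)
    stopifnot(length(a) == length(b))
    n01 <- sum(!a & b)
    n10 <- sum(a & !b)
    if (n01 + n10 == 0) return(1)
    return(stats::binom.test(n01, n01 + n10, p = 0.5)$p.value)
  }
  stopifnot(is.data.frame(a), is.data.frame(b), nrow(a) == nrow(b))
  n <- nrow(a)
  kap <- function(df, idx) {
    tab <- table(factor(df$pred[idx], levels = sort(unique(c(a$true, a$pred, b$pred)))),
                 factor(df$true[idx], levels = sort(unique(c(a$true, a$pred, b$pred)))))
    n_ <- sum(tab)
    po <- sum(diag(tab)) / n_
    pe <- sum(rowSums(tab) * colSums(tab)) / n_^2
    (po - pe) / (1 - pe)
  }
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    expr
  }
  diffs <- withr_seed({
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      kap(b, idx) - kap(a, idx)
    }, numeric(1))
  })
  p_lo <- (sum(diffs <= 0) + 1) / (n_boot + 1)
  p_hi <- (sum(diffs >= 0) + 1) / (n_boot + 1)
  min(1, 2 * min(p_lo, p_hi))
}
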