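test_that("Wilson continuity-corrected interval matches a direct evaluation of the formula", {
  z <- qnorm(0.975)
  oracle <- function(k, n) {
    p <- k / n
    lo <- if (k == 0) 0 else {
      (2 * n * p + z^2 - 1 -
         z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * (1 - p) + 1))) /
        (2 * (n + z^2))
    }
    hi <- if (k == n) 1 else {
      (2 * n * p + z^2 + 1 +
         z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * (1 - p) - 1))) /
        (2 * (n + z^2))
    }
    c(max(0, lo), min(1, hi))
  }
  for (case in list(c(231, 245), c(172, 245), c(16, 30), c(1, 10),
                    c(80, 106))) {
    expect_equal(wilson_ci(case[1], case[2]), oracle(case[1], case[2]),
                 tolerance = 1e-12)
  }
  expect_equal(wilson_ci(10, 10)[2], 1)
  expect_equal(wilson_ci(0, 10)[1], 0)
  expect_error(wilson_ci(3, 0))
})

test_that("ICC(A,1) equals the ANOVA mean-squares oracle and penalizes offsets", {
  rng <- local_rng(42)
  x <- rng$rnorm(10, 20, 6)
  y <- x + rng$rnorm(10, 1.5, 2)

  # independent oracle: two-way ANOVA via aov(), ICC assembled from the
  # printed mean squares
  df <- data.frame(value = c(x, y),
                   subj = factor(rep(1:10, 2)),
                   rater = factor(rep(1:2, each = 10)))
  ms <- summary(aov(value ~ subj + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- 10; k <- 2
  icc_oracle <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))

  got <- icc_absolute(x, y)
  expect_equal(got$icc, icc_oracle, tolerance = 1e-12)
  expect_true(got$conf_low <= got$icc && got$icc <= got$conf_high)

  expect_equal(icc_absolute(x, x)$icc, 1)
  expect_lt(icc_absolute(x, x + 5)$icc, 1)
  expect_error(icc_absolute(rep(1, 5), rep(2, 5)))
})

test_that("Bland-Altman limits match hand-computed moments and recover N(0,1) limits", {
  x <- c(10, 12, 9, 14, 11)
  y <- c(11, 11, 10, 16, 12)
  d <- y - x
  ba <- bland_altman(x, y)
  expect_equal(ba$estimate[ba$quantity == "bias"], mean(d))
  expect_equal(ba$estimate[ba$quantity == "loa_upper"],
               mean(d) + 1.96 * sd(d))
  expect_equal(ba$estimate[ba$quantity == "loa_lower"],
               mean(d) - 1.96 * sd(d))

  ba0 <- bland_altman(x, x)
  expect_equal(ba0$estimate, rep(0, 3))

  rng <- local_rng(7)
  xx <- rng$rnorm(10000, 30, 10)
  dd <- rng$rnorm(10000, 0, 1)
  ba2 <- bland_altman(xx, xx + dd)
  expect_equal(ba2$estimate[ba2$quantity == "loa_lower"], -1.96,
               tolerance = 0.05 / 1.96)
  expect_equal(ba2$estimate[ba2$quantity == "loa_upper"], 1.96,
               tolerance = 0.05 / 1.96)
})

test_that("ROC/PR AUC equals the pairwise Mann-Whitney oracle and pROC", {
  scores <- c(0.1, 0.4, 0.35, 0.8, 0.65, 0.2)
  labels <- c(0, 0, 1, 1, 1, 0)
  cr <- roc_pr_curves(scores, labels)
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(cr$auc_roc, mean(pairs), tolerance = 1e-12)
  skip_if_not_installed("pROC")
  expect_equal(cr$auc_roc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("perfect separation gives AUC 1 and label-free scores give AUC about 0.5", {
  expect_equal(roc_pr_curves(c(1, 2, 3, 7, 8, 9),
                             c(0, 0, 0, 1, 1, 1))$auc_roc, 1)
  rng <- local_rng(11)
  sc <- rng$runif(4000)
  lb <- rng$runif(4000) > 0.5
  expect_equal(roc_pr_curves(sc, lb)$auc_roc, 0.5, tolerance = 0.05)
  expect_error(roc_pr_curves(1:5, rep(1, 5)))
})

test_that("Cohen's kappa matches independent computation, with exact edge cases", {
  cm <- matrix(c(20, 5, 3, 12), 2, 2)
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kap <- cohen_kappa(cm)
  expect_equal(kap$kappa, (po - pe) / (1 - pe), tolerance = 1e-12)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  expect_equal(kap$conf_high - kap$kappa, qnorm(0.975) * se,
               tolerance = 1e-12)

  expect_equal(cohen_kappa(diag(c(5, 8, 2, 4)))$kappa, 1)
  # independence: outer product of marginals has kappa 0
  r <- c(10, 20, 30, 40); c_ <- c(25, 25, 25, 25)
  indep <- outer(r, c_) / 100
  expect_equal(cohen_kappa(indep)$kappa, 0, tolerance = 1e-12)
})

test_that("Simel likelihood-ratio intervals match a subject-level bootstrap", {
  n_pos <- 120; n_neg <- 150
  tp <- 95; tn <- 130
  sens <- tp / n_pos; spec <- tn / n_neg
  got <- lr_ci(sens, spec, n_pos, n_neg)

  rng <- local_rng(31)
  B <- 2000
  boots <- matrix(NA_real_, B, 2)
  labs <- rep(c(1, 0), c(n_pos, n_neg))
  preds <- c(rep(c(1, 0), c(tp, n_pos - tp)),
             rep(c(1, 0), c(n_neg - tn, tn)))
  for (b in seq_len(B)) {
    i <- rng$sample(length(labs), length(labs), replace = TRUE)
    s <- sum(preds[i] == 1 & labs[i] == 1) / sum(labs[i] == 1)
    sp <- sum(preds[i] == 0 & labs[i] == 0) / sum(labs[i] == 0)
    boots[b, ] <- c(s / (1 - sp), (1 - s) / sp)
  }
  bq <- unname(apply(boots, 2, quantile, c(0.025, 0.975), na.rm = TRUE))
  # log-method CI within Monte-Carlo tolerance of the bootstrap CI
  expect_equal(log(got$conf_low[1]), log(bq[1, 1]), tolerance = 0.15)
  expect_equal(log(got$conf_high[1]), log(bq[2, 1]), tolerance = 0.15)
  expect_equal(log(got$conf_low[2]), log(bq[1, 2]), tolerance = 0.15)
  expect_equal(log(got$conf_high[2]), log(bq[2, 2]), tolerance = 0.15)
})

test_that("degenerate likelihood-ratio cells give open intervals", {
  got <- lr_ci(1, 0.533, 215, 30)     # sens = 1 -> LR- = 0, open upper CI
  expect_equal(got$estimate[2], 0)
  expect_equal(got$conf_low[2], 0)
  expect_true(is.na(got$conf_high[2]))
  got2 <- lr_ci(0.8, 1, 100, 100)     # spec = 1 -> LR+ infinite
  expect_true(is.infinite(got2$estimate[1]))
})

test_that("Benjamini-Yekutieli thresholds, flags and reductions behave per definition", {
  # m = 1 reduces to p <= alpha
  expect_equal(benjamini_yekutieli(0.04)$n_rejected, 1)
  expect_equal(benjamini_yekutieli(0.06)$n_rejected, 0)
  # all p = 1: no rejections
  expect_equal(benjamini_yekutieli(rep(1, 10))$n_rejected, 0)
  # flags agree with stats::p.adjust(method = "BY") on random p-values
  rng <- local_rng(5)
  for (i in 1:20) {
    p <- rng$runif(rng$sample(30, 1))^2
    got <- benjamini_yekutieli(p, alpha = 0.05)
    expect_identical(got$tests$significant,
                     p.adjust(p, method = "BY") <= 0.05)
  }
  # threshold non-decreasing in alpha; flags monotone in p
  p <- c(0.001, 0.004, 0.02, 0.2, 0.6)
  th <- vapply(c(0.01, 0.05, 0.1, 0.2),
               function(a) benjamini_yekutieli(p, a)$threshold, 0)
  expect_true(all(diff(th) >= 0))
  g <- benjamini_yekutieli(p, 0.05)
  expect_true(all(diff(g$tests$significant[order(p)]) <= 0))
})

test_that("paired comparisons: exact McNemar equals the binomial tail and kappa bootstrap is seed-stable", {
  a <- rep(TRUE, 30)
  b <- c(rep(FALSE, 12), rep(TRUE, 18))
  a2 <- c(rep(TRUE, 28), FALSE, FALSE)
  # discordant (12, 2)
  disc_a <- sum(a2 & !b); disc_b <- sum(!a2 & b)
  p_pkg <- compare_paired(a2, b, kind = "proportion")
  p_oracle <- binom.test(min(disc_a, disc_b), disc_a + disc_b, 0.5)$p.value
  expect_equal(p_pkg, p_oracle, tolerance = 1e-12)
  expect_equal(compare_paired(a, a, kind = "proportion"), 1)

  rng <- local_rng(17)
  true_cls <- rng$sample(4, 60, replace = TRUE)
  da <- data.frame(pred = pmin(4, true_cls + (rng$runif(60) < 0.3)),
                   true = true_cls)
  db <- data.frame(pred = pmin(4, true_cls + (rng$runif(60) < 0.1)),
                   true = true_cls)
  p1 <- compare_paired(da, db, kind = "kappa", n_boot = 2000, seed = 1)
  p2 <- compare_paired(da, db, kind = "kappa", n_boot = 2000, seed = 1)
  expect_identical(p1, p2)
  expect_true(p1 >= 0 && p1 <= 1)
})
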