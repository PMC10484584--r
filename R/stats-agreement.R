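#' Intraclass correlation coefficient of absolute agreement, ICC(A,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC between
#' two raters/methods, with the F-based 95% confidence interval of
#' McGraw & Wong. Absolute agreement penalizes systematic offsets between the
#' methods, which is why a constant shift between `x` and `y` lowers the ICC
#' even when the correlation is perfect.
#'
#' @param x,y Numeric vectors of paired measurements (same subjects).
#' @param level Confidence level, default 0.95.
#' @return A one-row tibble with columns `icc`, `conf_low`, `conf_high`, `n`.
#' @export
icc_absolute <- function(x, y, level = 0.95) {
  stopifnot(length(x) == length(y), is.numeric(x), is.numeric(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("icc_absolute() needs at least 3 complete pairs")
  k <- 2
  dat <- cbind(x, y)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("icc_absolute(): zero variance in both methods; ICC undefined")
  }
  grand <- mean(dat)
  row_m <- rowMeans(dat)
  col_m <- colMeans(dat)
  # two-way ANOVA mean squares
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((dat - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  alpha <- 1 - level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - n - k) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - n - k) * mse + n * f_u * msr)

  tibble::tibble(icc = icc, conf_low = lower, conf_high = upper, n = n)
}

#' Bland-Altman bias and limits of agreement
#'
#' Differences are taken as `y - x` (estimate minus reference). The limits of
#' agreement are bias +/- 1.96 sd(d); the bias CI uses the t-based standard
#' error sd/sqrt(n) and each limit's CI uses the large-sample standard error
#' sd * sqrt(3/n).
#'
#' @param x Reference measurements.
#' @param y Estimated measurements.
#' @param level Confidence level, default 0.95.
#' @return A tibble with one row per quantity (`bias`, `loa_lower`,
#'   `loa_upper`) and columns `estimate`, `conf_low`, `conf_high`, `n`.
#' @export
bland_altman <- function(x, y, level = 0.95) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("bland_altman() needs at least 3 complete pairs")
  d <- y - x
  bias <- mean(d)
  s <- stats::sd(d)
  z <- stats::qnorm(1 - (1 - level) / 2)
  tcrit <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  loa_l <- bias - 1.96 * s
  loa_u <- bias + 1.96 * s
  se_bias <- s / sqrt(n)
  se_loa <- s * sqrt(3 / n)
  tibble::tibble(
    quantity = c("bias", "loa_lower", "loa_upper"),
    estimate = c(bias, loa_l, loa_u),
    conf_low = c(bias - tcrit * se_bias, loa_l - z * se_loa, loa_u - z * se_loa),
    conf_high = c(bias + tcrit * se_bias, loa_l + z * se_loa, loa_u + z * se_loa),
    n = n
  )
}

#' Bland-Altman plot for two paired index measurements
#'
#' @param x Reference values.
#' @param y Estimated values.
#' @param xlab,ylab Axis labels.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(x, y, xlab = "Mean of methods",
                              ylab = "Difference (estimate - reference)") {
  ba <- bland_altman(x, y)
  df <- tibble::tibble(m = (x + y) / 2, d = y - x)
  hl <- ba$estimate
  ggplot2::ggplot(df, ggplot2::aes(x = .data$m, y = .data$d)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = hl[1], colour = "steelblue") +
    ggplot2::geom_hline(yintercept = hl[2:3], linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_minimal()
}
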