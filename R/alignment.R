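#' Windowed normalized cross-correlation between two recordings
#'
#' Both signals are resampled to a common rate and, in moving windows of the
#' reference signal, the normalized cross-correlation against the other
#' signal is evaluated over lags up to `max_lag`; the per-window peak lag
#' and peak correlation are returned. A positive lag means the second
#' recording's clock is behind (`b(t) = a(t - lag)`).
#'
#' @param a Reference `waveform` (e.g. the PSG flow channel).
#' @param b Second `waveform` (e.g. the HSAT flow channel).
#' @param win Window length in seconds (>= 30).
#' @param step Step between window centers in seconds.
#' @param max_lag Maximum absolute lag searched, seconds.
#' @param rate Common analysis rate in Hz (default 10; breathing-band
#'   structure survives well below the native 100 Hz).
#' @return Tibble with columns `center`, `lag`, `peak_corr`.
#' @export
windowed_xcorr <- function(a, b, win = 120, step = 60, max_lag = 60,
                           rate = 10) {
  stopifnot(inherits(a, "waveform"), inherits(b, "waveform"), win >= 30)
  res <- function(w) {
    n <- floor(wf_duration(w) * rate)
    stats::approx(wf_times(w), w$samples, xout = (seq_len(n) - 1) / rate,
                  rule = 2)$y
  }
  xa <- res(a); xb <- res(b)
  nw <- round(win * rate)
  nl <- round(max_lag * rate)
  if (length(xa) < nw || length(xb) < nw) {
    stop("signals shorter than one correlation window")
  }
  starts <- seq(1, length(xa) - nw + 1, by = round(step * rate))
  rows <- lapply(starts, function(s0) {
    w <- xa[s0:(s0 + nw - 1)]
    w <- w - mean(w)
    nw_norm <- sqrt(sum(w^2))
    if (nw_norm < 1e-12) return(NULL)
    lags <- (-nl):nl
    b0 <- s0 + lags            # start index in xb for each lag
    ok <- b0 >= 1 & (b0 + nw - 1) <= length(xb)
    if (!any(ok)) return(NULL)
    # running sums over xb for per-lag normalization
    cs <- c(0, cumsum(xb))
    cs2 <- c(0, cumsum(xb^2))
    corr <- rep(NA_real_, length(lags))
    for (k in which(ok)) {
      i0 <- b0[k]
      seg <- xb[i0:(i0 + nw - 1)]
      num <- sum(w * seg) - 0  # w is zero-mean
      ssum <- cs[i0 + nw] - cs[i0]
      ssq <- cs2[i0 + nw] - cs2[i0]
      denom <- nw_norm * sqrt(max(ssq - ssum^2 / nw, 1e-12))
      corr[k] <- num / denom
    }
    pk <- which.max(corr)
    # parabolic interpolation around the peak for sub-sample lag accuracy
    frac <- 0
    if (pk > 1 && pk < length(corr) &&
        is.finite(corr[pk - 1]) && is.finite(corr[pk + 1])) {
      denom <- corr[pk - 1] - 2 * corr[pk] + corr[pk + 1]
      if (abs(denom) > 1e-12) {
        frac <- 0.5 * (corr[pk - 1] - corr[pk + 1]) / denom
        frac <- max(-0.5, min(0.5, frac))
      }
    }
    tibble::tibble(center = (s0 - 1 + nw / 2) / rate,
                   lag = (lags[pk] + frac) / rate,
                   peak_corr = corr[pk])
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) stop("no usable correlation windows")
  out
}

#' Fit a clock model (shift + drift) from windowed lags
#'
#' Robust (least-absolute-deviations, by iteratively reweighted least
#' squares) linear fit of `lag = shift + drift * center` over the windows
#' whose peak correlation reaches the admissibility threshold. At least two
#' admissible windows are required; otherwise alignment is declared
#' impossible (recordings with too-low signal quality cannot be aligned and
#' must be excluded).
#'
#' @param lags Tibble from [windowed_xcorr()].
#' @param corr_threshold Admissibility threshold on the peak correlation.
#' @return A `clock_model` list: `shift` (s), `drift` (s/s), `quality`
#'   (admissible fraction), `windows` (the admissible rows).
#' @export
fit_clock_model <- function(lags, corr_threshold = 0.5) {
  adm <- lags[is.finite(lags$peak_corr) &
                lags$peak_corr >= corr_threshold, , drop = FALSE]
  if (nrow(adm) < 2) {
    stop("alignment impossible: fewer than 2 windows with peak correlation >= ",
         corr_threshold)
  }
  x <- adm$center; y <- adm$lag
  # LAD via IRLS on top of OLS start
  beta <- stats::coef(stats::lm(y ~ x))
  for (it in 1:25) {
    r <- y - beta[1] - beta[2] * x
    wgt <- 1 / pmax(abs(r), 1e-6)
    fit <- stats::lm(y ~ x, weights = wgt)
    newb <- stats::coef(fit)
    if (max(abs(newb - beta)) < 1e-10) break
    beta <- newb
  }
  m <- list(shift = unname(beta[1]), drift = unname(beta[2]),
            quality = nrow(adm) / nrow(lags), windows = adm)
  if (abs(m$drift) >= 0.01) {
    stop("alignment impossible: implausible clock drift (|drift| >= 0.01)")
  }
  class(m) <- "clock_model"
  m
}

#' Align two recordings sharing a flow channel
#'
#' Convenience wrapper: windowed cross-correlation followed by the robust
#' clock-model fit.
#'
#' @param a,b `waveform`s of the shared channel.
#' @param ... Passed to [windowed_xcorr()] and [fit_clock_model()].
#' @return A `clock_model`.
#' @export
align_recordings <- function(a, b, ...) {
  args <- list(...)
  xc_args <- args[names(args) %in% c("win", "step", "max_lag", "rate")]
  fc_args <- args[names(args) %in% "corr_threshold"]
  lags <- do.call(windowed_xcorr, c(list(a, b), xc_args))
  do.call(fit_clock_model, c(list(lags), fc_args))
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("<clock_model> shift %.3f s, drift %.3g s/s, quality %.2f\n",
              x$shift, x$drift, x$quality))
  invisible(x)
}

#' Invert a clock model
#'
#' @param m A `clock_model`.
#' @return The inverse model: applying both in sequence is the identity.
#' @export
invert_clock_model <- function(m) {
  inv <- list(shift = -m$shift / (1 + m$drift),
              drift = 1 / (1 + m$drift) - 1,
              quality = m$quality, windows = m$windows)
  class(inv) <- "clock_model"
  inv
}

#' Apply a clock model to a waveform or annotation set
#'
#' Timestamps map as `t -> t * (1 + drift) + shift`; durations scale by
#' `(1 + drift)`. For waveforms the start offset and sampling rate are
#' adjusted; for annotation sets the event times and the recording duration
#' are transformed (the hypnogram keeps its epoch labels, padded or
#' truncated to the rescaled duration).
#'
#' @param x A `waveform` or `annotation_set`.
#' @param m A `clock_model`.
#' @return The aligned object.
#' @export
apply_alignment <- function(x, m) {
  stopifnot(inherits(m, "clock_model"))
  s <- 1 + m$drift
  if (inherits(x, "waveform")) {
    out <- x
    out$start <- x$start * s + m$shift
    out$rate <- x$rate / s
    return(out)
  }
  if (inherits(x, "annotation_set")) {
    ev <- x$events
    ev$onset <- ev$onset * s + m$shift
    ev$duration <- ev$duration * s
    new_dur <- x$rec_duration * s + m$shift
    n_new <- ceiling(new_dur / EPOCH_LEN)
    stages <- x$stages
    if (n_new > length(stages)) {
      stages <- c(stages, rep(stages[length(stages)],
                              n_new - length(stages)))
    } else {
      stages <- stages[seq_len(n_new)]
    }
    ev <- ev[ev$onset >= 0 & ev$onset + ev$duration <= new_dur, ,
             drop = FALSE]
    return(annotation_set(stages, ev, new_dur))
  }
  stop("apply_alignment() handles waveform or annotation_set objects")
}
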