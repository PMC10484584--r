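#' Preprocess a PPG waveform
#'
#' Resamples to 100 Hz and applies a zero-phase 0.3 Hz Butterworth high-pass
#' filter (order 2, forward-backward), removing DC and baseline drift
#' without shifting event times.
#'
#' @param w Input `waveform`.
#' @return A `waveform` at 100 Hz.
#' @export
preprocess_ppg <- function(w) {
  preprocess_highpass(w, rate = 100, cutoff = 0.3)
}

#' Preprocess a respiratory flow waveform
#'
#' Resamples to 10 Hz and applies a zero-phase 0.03 Hz high-pass filter.
#'
#' @param w Input `waveform`.
#' @return A `waveform` at 10 Hz.
#' @export
preprocess_flow <- function(w) {
  preprocess_highpass(w, rate = 10, cutoff = 0.03)
}

preprocess_highpass <- function(w, rate, cutoff) {
  stopifnot(inherits(w, "waveform"))
  if (length(w$samples) == 0) stop("empty waveform")
  x <- w$samples
  if (w$rate != rate) {
    n <- max(1, round(wf_duration(w) * rate))
    x <- stats::approx(wf_times(w), x, xout = w$start + (seq_len(n) - 1) / rate,
                       rule = 2)$y
  }
  x <- x - mean(x)   # remove DC first; filtfilt edge transients stay small
  if (length(x) < 12) {
    return(waveform(x, rate, label = w$label, start = w$start))
  }
  bf <- signal::butter(2, cutoff / (rate / 2), type = "high")
  y <- signal::filtfilt(bf, x)
  waveform(y, rate, label = w$label, start = w$start)
}
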