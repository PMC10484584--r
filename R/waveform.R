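#' Construct a waveform
#'
#' A uniformly sampled signal segment: channel label, sampling rate in Hz,
#' start offset in seconds from recording start, and the sample vector.
#'
#' @param samples Numeric vector of finite samples.
#' @param rate Sampling rate in Hz, > 0.
#' @param label Channel name.
#' @param start Offset of the first sample in seconds.
#' @return An object of class `waveform`.
#' @export
waveform <- function(samples, rate, label = "signal", start = 0) {
  stopifnot(is.numeric(samples), is.numeric(rate), length(rate) == 1,
            rate > 0, is.finite(start))
  if (any(!is.finite(samples))) stop("waveform samples must be finite")
  structure(list(label = as.character(label), rate = rate, start = start,
                 samples = as.numeric(samples)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> '%s' %.6g Hz, %d samples (%.1f s), start %.3f s\n",
              x$label, x$rate, length(x$samples),
              length(x$samples) / x$rate, x$start))
  invisible(x)
}

wf_duration <- function(w) length(w$samples) / w$rate

wf_times <- function(w) w$start + (seq_along(w$samples) - 1) / w$rate

#' Read waveforms from CSV or EDF
#'
#' The CSV dialect is: line 1 the header `label,rate_hz,start_s`, line 2 the
#' header values, and from line 3 one sample per line. EDF files are read
#' with the package's bundled EDF reader (16-bit European Data Format).
#'
#' @param path Input path.
#' @param format `"csv"` or `"edf"`; guessed from the extension by default.
#' @return A `waveform` (CSV) or a named list of `waveform`s (EDF).
#' @export
read_waveform <- function(path, format = c("auto", "csv", "edf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "edf") return(read_edf(path))
  lines <- readLines(path)
  if (length(lines) < 2 || trimws(lines[1]) != "label,rate_hz,start_s") {
    stop("malformed waveform CSV: expected header 'label,rate_hz,start_s'")
  }
  hdr <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
  if (length(hdr) != 3) stop("malformed waveform CSV header values")
  rate <- as.numeric(hdr[2])
  if (!is.finite(rate) || rate <= 0) stop("invalid sampling rate in header")
  samples <- as.numeric(lines[-(1:2)])
  if (anyNA(samples)) stop("non-numeric sample values")
  waveform(samples, rate, label = hdr[1], start = as.numeric(hdr[3]))
}

#' Write a waveform to CSV
#'
#' @param w A `waveform`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("label,rate_hz,start_s", con)
  writeLines(sprintf("%s,%.10g,%.10g", w$label, w$rate, w$start), con)
  writeLines(format(w$samples, digits = 10, scientific = FALSE, trim = TRUE),
             con)
  invisible(path)
}

# ---- minimal EDF (European Data Format) support -------------------------
# 16-bit EDF with one-second data records. Sample rates must therefore be
# positive integers. Written from scratch because the signal container is
# simple and fully specified by the published format: a 256-byte ASCII
# header, 256 ASCII bytes per signal, then little-endian int16 data records
# with linear digital-to-physical scaling.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write waveforms to an EDF file
#'
#' @param waves A `waveform` or list of `waveform`s with integer rates.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(waves, path) {
  if (inherits(waves, "waveform")) waves <- list(waves)
  stopifnot(length(waves) >= 1, all(vapply(waves, inherits, TRUE, "waveform")))
  rates <- vapply(waves, `[[`, numeric(1), "rate")
  if (any(rates != round(rates) | rates <= 0)) {
    stop("EDF writer requires positive integer sampling rates")
  }
  dur <- max(vapply(waves, wf_duration, numeric(1)))
  n_rec <- as.integer(ceiling(dur))
  ns <- length(waves)

  # per-signal physical range and digital scaling
  pmin <- pmax_ <- numeric(ns)
  digmin <- -32768L; digmax <- 32767L
  digital <- vector("list", ns)
  for (i in seq_len(ns)) {
    s <- waves[[i]]$samples
    lo <- min(s); hi <- max(s)
    if (hi - lo < 1e-12) { lo <- lo - 1; hi <- hi + 1 }
    pad <- (hi - lo) * 0.001
    pmin[i] <- lo - pad; pmax_[i] <- hi + pad
    need <- n_rec * rates[i]
    s <- c(s, rep(s[length(s)], need - length(s)))
    dig <- round((s - pmin[i]) / (pmax_[i] - pmin[i]) *
                   (digmax - digmin) + digmin)
    digital[[i]] <- as.integer(pmin(pmax(dig, digmin), digmax))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr_len <- 256L + 256L * ns
  wr <- function(x, width) writeChar(edf_pad(x, width), con, eos = NULL)
  wr("0", 8)                               # version
  wr("X X X X", 80)                        # patient id (anonymous)
  wr("Startdate X X X X", 80)              # recording id
  wr("01.01.00", 8); wr("00.00.00", 8)     # date, time
  wr(hdr_len, 8)
  wr("", 44)                               # reserved
  wr(n_rec, 8)
  wr("1", 8)                               # record duration (s)
  wr(ns, 4)
  for (w in waves) wr(w$label, 16)
  for (w in waves) wr("", 80)              # transducer
  for (w in waves) wr("au", 8)             # physical dimension
  for (i in seq_len(ns)) wr(formatC(pmin[i], digits = 6, format = "g"), 8)
  for (i in seq_len(ns)) wr(formatC(pmax_[i], digits = 6, format = "g"), 8)
  for (i in seq_len(ns)) wr(digmin, 8)
  for (i in seq_len(ns)) wr(digmax, 8)
  for (w in waves) wr("", 80)              # prefiltering
  for (i in seq_len(ns)) wr(rates[i], 8)   # samples per record
  for (i in seq_len(ns)) wr("", 32)        # reserved

  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1) * rates[i] + 1):(r * rates[i])
      writeBin(digital[[i]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path Path to a 16-bit EDF file.
#' @return Named list of `waveform`s.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("corrupt EDF header: bad version field")
  rd(80); rd(80); rd(8); rd(8)
  hdr_len <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1 || is.na(n_rec) || n_rec < 1 ||
      !is.finite(rec_dur) || rec_dur <= 0) {
    stop("corrupt EDF header")
  }
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  if (any(is.na(spr) | spr <= 0)) stop("corrupt EDF header: bad sample counts")
  for (i in seq_len(ns)) rd(32)

  per_rec <- sum(spr)
  all_raw <- readBin(con, integer(), n = n_rec * per_rec, size = 2,
                     endian = "little", signed = TRUE)
  if (length(all_raw) < n_rec * per_rec) stop("EDF file truncated")
  # signal index for one record, recycled across records
  sig_idx <- rep.int(seq_len(ns), spr)
  out <- vector("list", ns)
  for (i in seq_len(ns)) {
    raw_i <- all_raw[rep.int(sig_idx == i, n_rec)]
    phys <- pmin[i] + (raw_i - dmin[i]) / (dmax[i] - dmin[i]) *
      (pmax_[i] - pmin[i])
    out[[i]] <- waveform(phys, spr[i] / rec_dur, label = labels[i])
  }
  names(out) <- make.unique(labels)
  out
}
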