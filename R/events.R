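#' Construct a 2 Hz probability series
#'
#' The continuous arousal probability emitted by the detector: one value per
#' 0.5 s, all in `[0, 1]`.
#'
#' @param values Numeric vector in `[0, 1]`.
#' @param start Offset of the first sample in seconds.
#' @param rate Sampling rate, fixed at 2 Hz.
#' @return An object of class `probability_series`.
#' @export
probability_series <- function(values, start = 0, rate = 2) {
  stopifnot(rate == 2, all(is.finite(values)), all(values >= 0 & values <= 1))
  structure(list(values = as.numeric(values), start = start, rate = rate),
            class = "probability_series")
}

#' Convert a probability series to autonomic arousal events
#'
#' Maximal runs of samples whose probability strictly exceeds the threshold
#' become events when they span at least 2 s (4 consecutive samples at
#' 2 Hz, each sample covering 0.5 s). The event onset is the time of the
#' run's first sample and the duration is run length times 0.5 s.
#'
#' @param p A `probability_series` (or plain numeric vector at 2 Hz).
#' @param threshold Detection threshold in `[0, 1]`, exceeded strictly.
#' @param min_dur Minimum event duration in seconds (default 2).
#' @return Event tibble of `arousal_autonomic` events.
#' @export
probability_to_events <- function(p, threshold, min_dur = 2) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  if (inherits(p, "probability_series")) {
    values <- p$values; start <- p$start; rate <- p$rate
  } else {
    values <- as.numeric(p); start <- 0; rate <- 2
  }
  if (length(values) == 0) return(scored_events())
  above <- values > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  min_samples <- ceiling(min_dur * rate)
  keep <- r$values & r$lengths >= min_samples
  if (!any(keep)) return(scored_events())
  scored_events(
    type = "arousal_autonomic",
    onset = start + (starts[keep] - 1) / rate,
    duration = r$lengths[keep] / rate
  )
}

#' Match predicted against reference events and compute F1
#'
#' Greedy one-to-one matching in onset order: a predicted and a reference
#' event match iff their half-open intervals overlap. Unmatched predictions
#' are false positives, unmatched references false negatives. Precision,
#' recall and F1 use the 0/0 -> 0 convention.
#'
#' @param pred,ref Event tibbles (need `onset`, `duration`).
#' @return A list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1` and the
#'   matched index pairs.
#' @export
match_events <- function(pred, ref) {
  sort_ev <- function(e, who) {
    if (nrow(e) > 1 && is.unsorted(e$onset)) {
      warning(who, " events not sorted by onset; sorting")
      e <- e[order(e$onset), , drop = FALSE]
    }
    e
  }
  pred <- sort_ev(pred, "predicted")
  ref <- sort_ev(ref, "reference")
  np <- nrow(pred); nr <- nrow(ref)
  used_ref <- logical(nr)
  pairs <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("pred", "ref")))
  for (i in seq_len(np)) {
    p_on <- pred$onset[i]; p_off <- p_on + pred$duration[i]
    for (j in seq_len(nr)) {
      if (used_ref[j]) next
      r_on <- ref$onset[j]; r_off <- r_on + ref$duration[j]
      if (r_on >= p_off) break  # sorted: no later ref can overlap
      if (p_on < r_off && r_on < p_off) {
        used_ref[j] <- TRUE
        pairs <- rbind(pairs, c(i, j))
        break
      }
    }
  }
  tp <- nrow(pairs)
  fp <- np - tp
  fn <- nr - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
       f1 = f1, pairs = pairs)
}

#' Calibrate the detection threshold by maximizing pooled F1
#'
#' Grid search (step 0.01 by default) over thresholds: for each candidate,
#' events are extracted from every training subject's probability series,
#' matched against that subject's reference arousals, and TP/FP/FN pooled
#' over subjects; the threshold with maximal pooled F1 is returned, ties
#' broken toward the larger threshold.
#'
#' @param prob_list List of `probability_series` (one per training subject).
#' @param ref_list List of reference arousal event tibbles (same order).
#' @param grid Candidate thresholds (default `seq(0.01, 0.99, by = 0.01)`).
#' @return A list with `threshold`, `f1`, and the full `grid` tibble.
#' @export
calibrate_threshold <- function(prob_list, ref_list,
                                grid = seq(0.01, 0.99, by = 0.01)) {
  stopifnot(length(prob_list) == length(ref_list), length(prob_list) >= 1)
  if (all(vapply(ref_list, nrow, 0L) == 0)) {
    stop("no reference arousals in the training set")
  }
  f1s <- vapply(grid, function(thr) {
    tp <- fp <- fn <- 0
    for (s in seq_along(prob_list)) {
      m <- match_events(probability_to_events(prob_list[[s]], thr),
                        ref_list[[s]])
      tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }, numeric(1))
  best <- max(which(f1s == max(f1s)))  # tie-break toward larger threshold
  list(threshold = grid[best], f1 = f1s[best],
       grid = tibble::tibble(threshold = grid, f1 = f1s))
}

#' Stratified four-fold cross-validation assignment
#'
#' Subjects are partitioned into four folds, stratified by database tag so
#' each fold holds 25% (+/- 1 subject) of each database. Sampling is
#' pseudo-random without replacement and fully reproducible from the seed.
#'
#' @param subjects Data frame with columns `subject_id` and `database`.
#' @param seed Integer seed.
#' @param k Number of folds (default 4).
#' @return Tibble with `subject_id`, `database`, `fold` (0-based).
#' @export
make_folds <- function(subjects, seed = 1L, k = 4L) {
  stopifnot(all(c("subject_id", "database") %in% names(subjects)))
  rng <- local_rng(seed)
  out <- lapply(split(seq_len(nrow(subjects)), subjects$database), function(idx) {
    if (length(idx) < k) {
      warning("fewer than ", k, " subjects in a database; best-effort stratification")
    }
    perm <- idx[rng$sample(length(idx))]
    tibble::tibble(row = perm, fold = (seq_along(perm) - 1L) %% k)
  })
  out <- dplyr::bind_rows(out)
  out <- out[order(out$row), ]
  tibble::tibble(subject_id = subjects$subject_id,
                 database = subjects$database,
                 fold = out$fold)
}
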