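# Fixtures built in code, shared across test files.

# minimal annotation set: 4 epochs W N2 N2 W, one apnea and one hypopnea
tiny_annotations <- function() {
  ev <- scored_events(
    type = c("apnea_obstructive", "hypopnea", "desaturation",
             "arousal_cortical"),
    onset = c(35, 62, 100, 92),
    duration = c(12, 15, 12, 5),
    depth = c(NA, NA, 4, NA))
  annotation_set(c("W", "N2", "N2", "W"), ev, 120)
}

# random annotation set for property tests
random_annotations <- function(rng, rec_duration = 3600) {
  n_ep <- ceiling(rec_duration / 30)
  lv <- c("W", "N1", "N2", "N3", "R")
  stages <- c("W", lv[rng$sample(5, n_ep - 1, replace = TRUE)])
  n_ev <- rng$sample(15, 1)
  types <- c("apnea_obstructive", "apnea_central", "apnea_mixed",
             "hypopnea", "desaturation", "arousal_cortical",
             "arousal_autonomic")
  type <- types[rng$sample(length(types), n_ev, replace = TRUE)]
  onset <- rng$runif(n_ev, 0, rec_duration - 70)
  duration <- rng$runif(n_ev, 5, 60)
  depth <- ifelse(type == "desaturation", rng$runif(n_ev, 1, 8), NA_real_)
  annotation_set(stages, scored_events(type, onset, duration, depth),
                 rec_duration)
}

# independent brute-force run-length scanner (oracle for
# probability_to_events)
oracle_runs <- function(values, threshold, rate = 2, min_dur = 2) {
  out <- NULL
  i <- 1
  n <- length(values)
  while (i <= n) {
    if (values[i] > threshold) {
      j <- i
      while (j <= n && values[j] > threshold) j <- j + 1
      len <- j - i
      if (len / rate >= min_dur) {
        out <- rbind(out, c((i - 1) / rate, len / rate))
      }
      i <- j
    } else {
      i <- i + 1
    }
  }
  out
}

# brute-force per-event index counter (oracle for compute_indices); walks
# events one by one with explicit loops and no shared helpers
oracle_counts <- function(ann, arousal_type, mode, desat_window = 45,
                          arousal_window = 5) {
  ev <- ann$events
  stages <- ann$stages
  is_sleep_overlap <- function(on, dur) {
    first <- floor(on / 30)
    last <- ceiling((on + dur) / 30) - 1
    any(stages[seq(max(0, first), min(length(stages) - 1, last)) + 1] != "W")
  }
  # wake-filtered arousals of the requested type
  ar <- ev[ev$type == arousal_type, , drop = FALSE]
  keep <- logical(nrow(ar))
  wake <- stages == "W"
  for (i in seq_len(nrow(ar))) {
    t <- ar$onset[i]
    epi <- floor(t / 30) + 1
    if (epi > length(stages)) next
    if (!wake[epi]) { keep[i] <- TRUE; next }
    a <- epi; while (a > 1 && wake[a - 1]) a <- a - 1
    b <- epi; while (b < length(stages) && wake[b + 1]) b <- b + 1
    run_start <- (a - 1) * 30; run_end <- b * 30
    keep[i] <- (t < run_start + 15) || (t >= run_end - 15)
  }
  ar <- ar[keep, , drop = FALSE]

  apn <- ev[ev$type %in% c("apnea_obstructive", "apnea_central",
                           "apnea_mixed"), , drop = FALSE]
  hyp <- ev[ev$type == "hypopnea", , drop = FALSE]
  des <- ev[ev$type == "desaturation" & !is.na(ev$depth) & ev$depth >= 3, ,
            drop = FALSE]
  n_ap <- 0
  for (i in seq_len(nrow(apn))) {
    if (is_sleep_overlap(apn$onset[i], apn$duration[i])) n_ap <- n_ap + 1
  }
  hyp_sleep <- logical(nrow(hyp))
  for (i in seq_len(nrow(hyp))) {
    hyp_sleep[i] <- is_sleep_overlap(hyp$onset[i], hyp$duration[i])
  }
  hyp <- hyp[hyp_sleep, , drop = FALSE]
  # greedy one-to-one desat pairing by |desat onset - hypopnea end|
  conf <- logical(nrow(hyp))
  if (nrow(hyp) && nrow(des)) {
    cand <- NULL
    for (h in seq_len(nrow(hyp))) {
      for (d in seq_len(nrow(des))) {
        hend <- hyp$onset[h] + hyp$duration[h]
        if (des$onset[d] >= hyp$onset[h] &&
            des$onset[d] <= hend + desat_window) {
          cand <- rbind(cand, c(h, d, abs(des$onset[d] - hend)))
        }
      }
    }
    if (!is.null(cand)) {
      cand <- cand[order(cand[, 3]), , drop = FALSE]
      used <- logical(nrow(des))
      for (r in seq_len(nrow(cand))) {
        if (!conf[cand[r, 1]] && !used[cand[r, 2]]) {
          conf[cand[r, 1]] <- TRUE
          used[cand[r, 2]] <- TRUE
        }
      }
    }
  }
  if (mode == "desat_or_arousal" && nrow(ar)) {
    for (h in which(!conf)) {
      hend <- hyp$onset[h] + hyp$duration[h]
      if (any(ar$onset >= hyp$onset[h] & ar$onset <= hend + arousal_window)) {
        conf[h] <- TRUE
      }
    }
  }
  list(n_events = n_ap + sum(conf), n_arousals = nrow(ar))
}
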