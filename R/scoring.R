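#' Keep respiratory events that overlap a sleep epoch
#'
#' Apneas and hypopneas are counted only if their half-open interval
#' intersects at least one epoch staged as sleep; events entirely within
#' wake epochs are discarded. Non-respiratory events pass through untouched.
#'
#' @param events Event tibble.
#' @param stages Hypnogram stage vector.
#' @return Filtered event tibble.
#' @export
filter_respiratory_events <- function(events, stages) {
  if (nrow(events) == 0) return(events)
  keep <- vapply(seq_len(nrow(events)), function(i) {
    if (!events$type[i] %in% RESP_TYPES) return(TRUE)
    ep <- epochs_overlapped(events$onset[i], events$duration[i],
                            length(stages))
    any(stages[ep] != "W")
  }, logical(1))
  events[keep, , drop = FALSE]
}

#' Keep arousals that start during sleep or at the edges of a wake period
#'
#' An arousal is retained when its onset falls in a sleep epoch, or within
#' the first or last 15 s of a maximal run of wake epochs. The 15-s
#' tolerance captures arousals that led to awakenings.
#'
#' @param arousals Event tibble of arousal events.
#' @param stages Hypnogram stage vector.
#' @param tolerance Edge tolerance within wake runs, seconds (default 15).
#' @return Filtered arousal tibble.
#' @export
filter_arousals <- function(arousals, stages, tolerance = 15) {
  if (nrow(arousals) == 0) return(arousals)
  n <- length(stages)
  wake <- stages == "W"
  # maximal runs of wake epochs -> [start, end) second intervals
  r <- rle(wake)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  wake_runs <- cbind(start = (starts[r$values] - 1) * EPOCH_LEN,
                     end = ends[r$values] * EPOCH_LEN)
  keep <- vapply(arousals$onset, function(t) {
    if (t >= n * EPOCH_LEN) return(FALSE)
    if (stage_at(stages, t) != "W") return(TRUE)
    run <- wake_runs[wake_runs[, "start"] <= t & t < wake_runs[, "end"], ,
                     drop = FALSE]
    t < run[1, "start"] + tolerance || t >= run[1, "end"] - tolerance
  }, logical(1))
  arousals[keep, , drop = FALSE]
}

#' Confirm hypopneas by desaturations and/or arousals
#'
#' A hypopnea is confirmed when an associated >= `min_depth` percent
#' desaturation starts within `[onset, end + desat_window]`, or - in mode
#' `desat_or_arousal` - when an associated arousal starts within
#' `[onset, end + arousal_window]`. Desaturations are paired one-to-one,
#' greedily by proximity of the desaturation onset to the hypopnea end, so
#' a single desaturation never confirms two hypopneas. Apneas are never
#' subject to confirmation.
#'
#' @param hypopneas Tibble of hypopnea events.
#' @param desats Tibble of desaturation events (with `depth`).
#' @param arousals Tibble of arousal events (already wake-filtered when
#'   used for index scoring).
#' @param mode `"desat_only"` or `"desat_or_arousal"`.
#' @param desat_window Association window after hypopnea end, seconds.
#' @param arousal_window Association window after hypopnea end, seconds.
#' @param min_depth Minimum desaturation depth in percent (default 3).
#' @return The confirmed subset of `hypopneas`.
#' @export
confirm_hypopneas <- function(hypopneas, desats, arousals = NULL,
                              mode = c("desat_only", "desat_or_arousal"),
                              desat_window = 45, arousal_window = 5,
                              min_depth = 3) {
  mode <- match.arg(mode)
  nh <- nrow(hypopneas)
  if (nh == 0) return(hypopneas)
  confirmed <- logical(nh)

  desats <- desats[!is.na(desats$depth) & desats$depth >= min_depth, ,
                   drop = FALSE]
  if (nrow(desats) > 0) {
    # greedy one-to-one pairing: candidate (hypopnea, desat) pairs ranked by
    # |desat onset - hypopnea end|
    hend <- hypopneas$onset + hypopneas$duration
    cand <- expand.grid(h = seq_len(nh), d = seq_len(nrow(desats)))
    ok <- desats$onset[cand$d] >= hypopneas$onset[cand$h] &
      desats$onset[cand$d] <= hend[cand$h] + desat_window
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand)) {
      cand$gap <- abs(desats$onset[cand$d] - hend[cand$h])
      cand <- cand[order(cand$gap), , drop = FALSE]
      used_d <- logical(nrow(desats))
      for (i in seq_len(nrow(cand))) {
        h <- cand$h[i]; d <- cand$d[i]
        if (!confirmed[h] && !used_d[d]) {
          confirmed[h] <- TRUE
          used_d[d] <- TRUE
        }
      }
    }
  }

  if (mode == "desat_or_arousal" && !is.null(arousals) && nrow(arousals)) {
    hend <- hypopneas$onset + hypopneas$duration
    for (h in which(!confirmed)) {
      hit <- arousals$onset >= hypopneas$onset[h] &
        arousals$onset <= hend[h] + arousal_window
      if (any(hit)) confirmed[h] <- TRUE
    }
  }
  hypopneas[confirmed, , drop = FALSE]
}

#' Severity class of an event index
#'
#' Left-closed bins at 5, 15 and 30 events/h: None `[0, 5)`, Mild `[5, 15)`,
#' Moderate `[15, 30)`, Severe `[30, Inf)`.
#'
#' @param index Non-negative event index (events per hour), vectorized.
#' @return Character vector of severity classes.
#' @export
severity_class <- function(index) {
  if (any(index < 0)) stop("index must be >= 0")
  cut(index, breaks = c(-Inf, 5, 15, 30, Inf), right = FALSE,
      labels = SEVERITY_LEVELS) |> as.character()
}

count_resp_events <- function(events, stages = NULL, arousals = NULL,
                              mode = "desat_only", windows = list()) {
  desat_window <- windows$desat_window %||% 45
  arousal_window <- windows$arousal_window %||% 5
  apneas <- events[events$type %in% c("apnea_obstructive", "apnea_central",
                                      "apnea_mixed"), , drop = FALSE]
  hyps <- events[events$type == "hypopnea", , drop = FALSE]
  desats <- events[events$type == "desaturation", , drop = FALSE]
  if (!is.null(stages)) {
    apneas <- filter_respiratory_events(apneas, stages)
    hyps <- filter_respiratory_events(hyps, stages)
  }
  hyps <- confirm_hypopneas(hyps, desats, arousals, mode = mode,
                            desat_window = desat_window,
                            arousal_window = arousal_window)
  nrow(apneas) + nrow(hyps)
}

#' Compute all per-subject indices
#'
#' From the reference (PSG) and estimated (HSAT) annotation sets of one
#' subject, computes:
#' * `ahi_psg`: apneas + hypopneas (confirmed by desaturations >= 3% or
#'   cortical arousals) overlapping sleep, per hour of reference sleep;
#' * `rei`: apneas + desaturation-confirmed hypopneas per hour of recording
#'   time - no sleep filtering (sleep is unknown to a bare HSAT);
#' * `ahi_cress`: sleep-filtered apneas + desaturation-confirmed hypopneas
#'   per hour of estimated sleep;
#' * `ahi_cress_autar`: as `ahi_cress` but hypopneas may also be confirmed
#'   by (wake-filtered) autonomic arousals;
#' * `ari` / `autari`: wake-filtered cortical / autonomic arousals per hour
#'   of the respective sleep time;
#' * `oai` / `cai`: obstructive / central apneas per hour of reference
#'   sleep.
#'
#' @param psg_ref Reference `annotation_set` (cortical arousals, PSG
#'   hypnogram).
#' @param hsat_est Estimated `annotation_set` (autonomic arousals, estimated
#'   hypnogram, HSAT-scored respiratory events).
#' @param windows Optional list with `desat_window` and `arousal_window`
#'   association windows in seconds (defaults 45 and 5).
#' @param subject_id Optional identifier carried into the report.
#' @return A one-row tibble (`index_report`) with all indices (events/h),
#'   sleep times (h) and severity classes.
#' @export
compute_indices <- function(psg_ref, hsat_est, windows = list(),
                            subject_id = NA_character_) {
  stopifnot(inherits(psg_ref, "annotation_set"),
            inherits(hsat_est, "annotation_set"))
  tst_ref <- total_sleep_time(psg_ref) / 3600
  tst_est <- total_sleep_time(hsat_est) / 3600
  rec_h <- hsat_est$rec_duration / 3600

  ref_ev <- psg_ref$events
  est_ev <- hsat_est$events
  cort <- filter_arousals(
    ref_ev[ref_ev$type == "arousal_cortical", , drop = FALSE],
    psg_ref$stages)
  auto <- filter_arousals(
    est_ev[est_ev$type == "arousal_autonomic", , drop = FALSE],
    hsat_est$stages)

  n_psg <- count_resp_events(ref_ev, psg_ref$stages, cort,
                             mode = "desat_or_arousal", windows = windows)
  n_rei <- count_resp_events(est_ev, stages = NULL,
                             mode = "desat_only", windows = windows)
  n_cress <- count_resp_events(est_ev, hsat_est$stages,
                               mode = "desat_only", windows = windows)
  n_autar <- count_resp_events(est_ev, hsat_est$stages, auto,
                               mode = "desat_or_arousal", windows = windows)

  per_h <- function(k, hours) {
    if (hours <= 0) {
      if (k > 0) stop("events present but sleep time is zero; index undefined")
      return(0)
    }
    k / hours
  }
  ref_sleep_filtered <- filter_respiratory_events(ref_ev, psg_ref$stages)
  oai <- per_h(sum(ref_sleep_filtered$type == "apnea_obstructive"), tst_ref)
  cai <- per_h(sum(ref_sleep_filtered$type == "apnea_central"), tst_ref)

  rep <- tibble::tibble(
    subject_id = subject_id,
    ahi_psg = per_h(n_psg, tst_ref),
    rei = per_h(n_rei, rec_h),
    ahi_cress = per_h(n_cress, tst_est),
    ahi_cress_autar = per_h(n_autar, tst_est),
    ari = per_h(nrow(cort), tst_ref),
    autari = per_h(nrow(auto), tst_est),
    oai = oai, cai = cai,
    tst_ref_h = tst_ref, tst_est_h = tst_est, rec_h = rec_h
  )
  rep$class_psg <- severity_class(rep$ahi_psg)
  rep$class_rei <- severity_class(rep$rei)
  rep$class_cress <- severity_class(rep$ahi_cress)
  rep$class_autar <- severity_class(rep$ahi_cress_autar)
  rep
}

`%||%` <- function(a, b) if (is.null(a)) b else a
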