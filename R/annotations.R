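STAGE_LEVELS <- c("W", "N1", "N2", "N3", "R")
EVENT_TYPES <- c("arousal_cortical", "arousal_autonomic", "apnea_obstructive",
                 "apnea_central", "apnea_mixed", "hypopnea", "desaturation")
RESP_TYPES <- c("apnea_obstructive", "apnea_central", "apnea_mixed", "hypopnea")
EPOCH_LEN <- 30

#' Construct an empty scored-event table
#'
#' Events are kept as a tibble with one row per event: `type` (one of the
#' seven scored types), `onset` and `duration` in seconds from recording
#' start, and `depth` (percent, desaturations only, otherwise `NA`). All
#' event intervals are half-open `[onset, onset + duration)`.
#'
#' @param type,onset,duration,depth Event fields (recycled per tibble rules).
#' @return A tibble with the four event columns.
#' @export
scored_events <- function(type = character(), onset = numeric(),
                          duration = numeric(), depth = NA_real_) {
  ev <- tibble::tibble(type = as.character(type), onset = as.numeric(onset),
                       duration = as.numeric(duration),
                       depth = as.numeric(depth))
  if (nrow(ev) == 0) ev$depth <- numeric(0)
  ev
}

validate_events <- function(events, rec_duration) {
  stopifnot(is.data.frame(events))
  need <- c("type", "onset", "duration")
  if (!all(need %in% names(events))) {
    stop("events must have columns type, onset, duration")
  }
  if (!"depth" %in% names(events)) events$depth <- NA_real_
  bad <- setdiff(unique(events$type), EVENT_TYPES)
  if (length(bad)) stop("unknown event type(s): ", paste(bad, collapse = ", "))
  if (any(!is.finite(events$onset)) || any(!is.finite(events$duration))) {
    stop("event onset/duration must be finite")
  }
  if (any(events$onset < 0)) stop("event onset must be >= 0")
  if (any(events$duration <= 0)) stop("event duration must be > 0")
  if (any(events$onset + events$duration > rec_duration + 1e-9)) {
    stop("event extends past the end of the recording")
  }
  d <- events$depth[events$type == "desaturation"]
  if (any(!is.na(d) & d < 0)) stop("desaturation depth must be >= 0")
  tibble::as_tibble(events[c("type", "onset", "duration", "depth")])
}

#' Construct an annotation set
#'
#' An annotation set bundles everything scored for one recording: a 30-s
#' epoch hypnogram, the scored events, and the recording duration. The
#' hypnogram must have `ceiling(rec_duration / 30)` epochs (the final epoch
#' may cover a partial interval).
#'
#' @param stages Character vector of sleep stages over W, N1, N2, N3, R.
#' @param events Event tibble as from [scored_events()].
#' @param rec_duration Recording duration in seconds.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(stages, events = scored_events(), rec_duration) {
  stages <- as.character(stages)
  if (!all(stages %in% STAGE_LEVELS)) {
    stop("stages must be in {", paste(STAGE_LEVELS, collapse = ", "), "}")
  }
  stopifnot(is.numeric(rec_duration), length(rec_duration) == 1,
            is.finite(rec_duration), rec_duration > 0)
  if (length(stages) != ceiling(rec_duration / EPOCH_LEN)) {
    stop("hypnogram must have ceiling(rec_duration/30) = ",
         ceiling(rec_duration / EPOCH_LEN), " epochs, got ", length(stages))
  }
  events <- validate_events(events, rec_duration)
  structure(list(stages = stages, epoch_len = EPOCH_LEN, events = events,
                 rec_duration = rec_duration),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %.0f s, %d epochs (%d sleep), %d events\n",
              x$rec_duration, length(x$stages), sum(x$stages != "W"),
              nrow(x$events)))
  if (nrow(x$events)) print(dplyr::count(x$events, .data$type))
  invisible(x)
}

#' Sleep stage at a time point
#'
#' Epoch `i` covers the half-open interval `[30 i, 30 (i + 1))` seconds.
#'
#' @param stages Hypnogram stage vector.
#' @param t Time in seconds from recording start.
#' @return The stage label at `t`.
#' @export
stage_at <- function(stages, t) {
  if (inherits(stages, "annotation_set")) stages <- stages$stages
  if (any(t < 0 | t >= EPOCH_LEN * length(stages))) {
    stop("t outside the hypnogram (need 0 <= t < ",
         EPOCH_LEN * length(stages), ")")
  }
  stages[floor(t / EPOCH_LEN) + 1]
}

#' Total sleep time of a hypnogram
#'
#' Sums 30 s per non-wake epoch. If `rec_duration` is supplied and the final
#' epoch is partial, it contributes its full 30 s only when it covers at
#' least 15 s of recording; otherwise it contributes pro rata, which avoids
#' inflating TST from a sliver of a final epoch.
#'
#' @param stages Hypnogram stage vector (or an `annotation_set`).
#' @param rec_duration Optional recording duration in seconds.
#' @return Total sleep time in seconds.
#' @export
total_sleep_time <- function(stages, rec_duration = NULL) {
  if (inherits(stages, "annotation_set")) {
    if (is.null(rec_duration)) rec_duration <- stages$rec_duration
    stages <- stages$stages
  }
  n <- length(stages)
  if (n == 0) return(0)
  full <- sum(stages != "W") * EPOCH_LEN
  if (is.null(rec_duration)) return(full)
  rem <- rec_duration - EPOCH_LEN * (n - 1)
  if (rem < EPOCH_LEN && rem < 15 && stages[n] != "W") {
    full <- full - EPOCH_LEN + rem
  }
  full
}

# Epoch indices (1-based) that an event's half-open interval overlaps.
epochs_overlapped <- function(onset, duration, n_epochs) {
  first <- floor(onset / EPOCH_LEN) + 1
  last <- ceiling((onset + duration) / EPOCH_LEN)
  seq(max(1, first), min(n_epochs, last))
}

#' Read an annotation set from its canonical JSON form
#'
#' The schema (version 1) is a single JSON object:
#' `{"schema_version": 1, "rec_duration_s": x, "epoch_len_s": 30,
#'   "stages": ["W", ...], "events": [{"type": t, "onset_s": o,
#'   "duration_s": d, "depth_pct": p|null}, ...]}`.
#'
#' @param path Path to a JSON file.
#' @return An `annotation_set`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE)
  for (f in c("rec_duration_s", "epoch_len_s", "stages")) {
    if (is.null(doc[[f]])) stop("annotation file missing field '", f, "'")
  }
  if (doc$epoch_len_s != EPOCH_LEN) {
    stop("unsupported epoch_len_s: ", doc$epoch_len_s)
  }
  ev <- doc$events
  events <- if (is.null(ev) || length(ev) == 0 ||
                (is.data.frame(ev) && nrow(ev) == 0)) {
    scored_events()
  } else {
    if (!is.data.frame(ev)) stop("field 'events' must be an array of objects")
    if (is.null(ev$depth_pct)) ev$depth_pct <- NA_real_
    scored_events(ev$type, ev$onset_s, ev$duration_s, ev$depth_pct)
  }
  annotation_set(doc$stages, events, doc$rec_duration_s)
}

#' Write an annotation set to canonical JSON
#'
#' Serialization is canonical: fixed field order, events sorted by onset
#' then type, so that write-read round-trips are identities on canonical
#' form.
#'
#' @param a An `annotation_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(a, path) {
  stopifnot(inherits(a, "annotation_set"))
  ev <- a$events[order(a$events$onset, a$events$type), , drop = FALSE]
  doc <- list(
    schema_version = 1L,
    rec_duration_s = a$rec_duration,
    epoch_len_s = EPOCH_LEN,
    stages = a$stages,
    events = lapply(seq_len(nrow(ev)), function(i) {
      list(type = ev$type[i], onset_s = ev$onset[i],
           duration_s = ev$duration[i],
           depth_pct = if (is.na(ev$depth[i])) NULL else ev$depth[i])
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
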