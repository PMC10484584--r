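#' Score every subject of a cohort
#'
#' Runs [compute_indices()] on each subject record and binds the one-row
#' reports into a tibble.
#'
#' @param cohort List of `subject_record`s.
#' @param windows Association-window configuration for
#'   [compute_indices()].
#' @return Tibble with one row per subject.
#' @export
score_cohort <- function(cohort, windows = list()) {
  dplyr::bind_rows(lapply(cohort, function(s) {
    compute_indices(s$psg_ref, s$hsat_est, windows = windows,
                    subject_id = s$subject_id)
  }))
}

#' Detect autonomic arousals for one subject and rescore
#'
#' Replaces the estimated annotation set's autonomic arousals with events
#' detected by the model at the given threshold, then recomputes all
#' indices.
#'
#' @param model Trained `arousal_model`.
#' @param record A `subject_record` with `waveforms$ppg` and
#'   `waveforms$flow`.
#' @param threshold Detection threshold from [calibrate_threshold()].
#' @param windows Association windows for [compute_indices()].
#' @return One-row index report tibble.
#' @export
detect_and_score <- function(model, record, threshold, windows = list()) {
  pred <- predict_arousal(model, record$waveforms$ppg,
                          record$waveforms$flow)
  det <- probability_to_events(pred$prob, threshold)
  est <- record$hsat_est
  ev <- est$events[est$events$type != "arousal_autonomic", , drop = FALSE]
  ev <- dplyr::bind_rows(ev, det)
  est2 <- annotation_set(est$stages, ev, est$rec_duration)
  compute_indices(record$psg_ref, est2, windows = windows,
                  subject_id = record$subject_id)
}

#' Four-fold cross-validated training, detection and scoring
#'
#' Subjects are split into four database-stratified folds. For each fold,
#' a model is trained (two phases: cardiac, then end-to-end with the
#' cardiac module frozen) on the other three folds, the detection threshold
#' is calibrated by maximizing F1 on the training folds, and autonomic
#' arousals are detected and scored on the held-out fold only. Every
#' subject is therefore scored exactly once, by a model that never saw it.
#'
#' @param cohort List of `subject_record`s.
#' @param model_cfg A `model_config`.
#' @param fold_seed Seed for the fold assignment.
#' @param tc_cardiac,tc_e2e `train_config`s for the two phases; their seeds
#'   are offset by the fold index so each fold's run is independent but
#'   reproducible.
#' @param windows Association windows for scoring.
#' @return A list with `reports` (per-subject index tibble), `manifest`
#'   (folds, thresholds, seeds, cardiac hashes) and `folds`.
#' @export
run_crossval <- function(cohort, model_cfg = model_config(), fold_seed = 1L,
                         tc_cardiac = train_config("cardiac"),
                         tc_e2e = train_config("end2end"),
                         windows = list()) {
  subjects <- tibble::tibble(
    subject_id = vapply(cohort, `[[`, "", "subject_id"),
    database = vapply(cohort, `[[`, "", "database"))
  folds <- make_folds(subjects, seed = fold_seed)
  reports <- list()
  manifest <- list()
  for (f in sort(unique(folds$fold))) {
    val_ids <- folds$subject_id[folds$fold == f]
    train_idx <- which(!subjects$subject_id %in% val_ids)
    val_idx <- which(subjects$subject_id %in% val_ids)
    stopifnot(length(intersect(train_idx, val_idx)) == 0)
    tcc <- tc_cardiac; tcc$seed <- tc_cardiac$seed + f
    tce <- tc_e2e; tce$seed <- tc_e2e$seed + f
    model <- build_model(model_cfg, seed = fold_seed + f)
    model <- train_cardiac(model, cohort[train_idx], tcc)
    hash_before <- cardiac_hash(model)
    model <- train_end2end(model, cohort[train_idx], tce)
    stopifnot(identical(cardiac_hash(model), hash_before))
    probs <- lapply(cohort[train_idx], function(s) {
      predict_arousal(model, s$waveforms$ppg, s$waveforms$flow)$prob
    })
    refs <- lapply(cohort[train_idx], function(s) {
      ev <- s$psg_ref$events
      ev[ev$type == "arousal_cortical", , drop = FALSE]
    })
    cal <- calibrate_threshold(probs, refs)
    reports[[length(reports) + 1]] <- dplyr::bind_rows(
      lapply(cohort[val_idx], function(s) {
        detect_and_score(model, s, cal$threshold, windows = windows)
      }))
    manifest[[length(manifest) + 1]] <- tibble::tibble(
      fold = f, threshold = cal$threshold, train_f1 = cal$f1,
      seed_cardiac = tcc$seed, seed_e2e = tce$seed,
      cardiac_hash = hash_before,
      n_train = length(train_idx), n_val = length(val_idx))
  }
  list(reports = dplyr::bind_rows(reports),
       manifest = dplyr::bind_rows(manifest),
       folds = folds)
}

#' Summarize severity confusion tables into diagnostic metric tables
#'
#' From 4x4 confusion matrices (one per AHI surrogate), computes the binary
#' diagnostic metrics at AHI cuts 5/15/30 and the four-class metrics, i.e.
#' the full evaluation tables. Externally supplied counts are accepted, so
#' published confusion tables can be re-evaluated without any model.
#'
#' @param cms Named list of 4x4 confusion matrices.
#' @param level Confidence level.
#' @return A list with `binary` (tibble: index, cut, metric, estimate, CI)
#'   and `fourclass` (tibble: index, metric, estimate, CI, count).
#' @export
summarize_confusion <- function(cms, level = 0.95) {
  binary <- dplyr::bind_rows(lapply(names(cms), function(nm) {
    dplyr::bind_rows(lapply(c(5, 15, 30), function(cut) {
      dplyr::mutate(binary_metrics(cms[[nm]], cut, level),
                    index = nm, cut = cut, .before = 1)
    }))
  }))
  fourclass <- dplyr::bind_rows(lapply(names(cms), function(nm) {
    dplyr::mutate(fourclass_metrics(cms[[nm]], level), index = nm,
                  .before = 1)
  }))
  list(binary = binary, fourclass = fourclass)
}

#' Evaluate per-subject index reports against the PSG reference
#'
#' Builds the severity confusion tables of the three HSAT surrogates
#' against `ahi_psg` and summarizes them with [summarize_confusion()];
#' also returns agreement statistics (ICC of absolute agreement and
#' Bland-Altman) per surrogate.
#'
#' @param reports Tibble from [score_cohort()] or [run_crossval()].
#' @param level Confidence level.
#' @return A list with `confusion`, `binary`, `fourclass`, `agreement`.
#' @export
run_evaluation <- function(reports, level = 0.95) {
  stopifnot(nrow(reports) >= 2)
  need <- c("ahi_psg", "rei", "ahi_cress", "ahi_cress_autar")
  if (!all(need %in% names(reports))) {
    stop("reports must contain columns: ", paste(need, collapse = ", "))
  }
  true_cls <- severity_class(reports$ahi_psg)
  cms <- list(
    rei = confusion4(severity_class(reports$rei), true_cls),
    ahi_cress = confusion4(severity_class(reports$ahi_cress), true_cls),
    ahi_cress_autar = confusion4(severity_class(reports$ahi_cress_autar),
                                 true_cls))
  smry <- summarize_confusion(cms, level)
  agreement <- dplyr::bind_rows(lapply(
    c("rei", "ahi_cress", "ahi_cress_autar"), function(nm) {
      icc_res <- tryCatch(icc_absolute(reports$ahi_psg, reports[[nm]], level),
                          error = function(e) {
                            tibble::tibble(icc = NA_real_,
                                           conf_low = NA_real_,
                                           conf_high = NA_real_,
                                           n = nrow(reports))
                          })
      ba <- bland_altman(reports$ahi_psg, reports[[nm]], level)
      tibble::tibble(index = nm, icc = icc_res$icc,
                     icc_low = icc_res$conf_low,
                     icc_high = icc_res$conf_high,
                     bias = ba$estimate[ba$quantity == "bias"],
                     loa_lower = ba$estimate[ba$quantity == "loa_lower"],
                     loa_upper = ba$estimate[ba$quantity == "loa_upper"])
    }))
  c(list(confusion = cms), smry, list(agreement = agreement))
}
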