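test_that("respiratory events are kept iff they overlap a sleep epoch", {
  st <- c("W", "N2", "W")
  ev <- scored_events(
    type = rep("apnea_obstructive", 3),
    onset = c(5, 25, 65),       # wholly in W; spans W->N2; wholly in W epoch 3
    duration = c(10, 10, 20))
  kept <- filter_respiratory_events(ev, st)
  expect_equal(kept$onset, 25)  # the boundary-spanning event is kept
  # all-sleep hypnogram: identity
  expect_equal(nrow(filter_respiratory_events(ev, c("N2", "N2", "N2"))), 3)
  # non-respiratory events pass through
  ar <- scored_events("arousal_cortical", 5, 5)
  expect_equal(nrow(filter_respiratory_events(ar, st)), 1)
})

test_that("arousals are kept when starting in sleep or within 15 s of a wake-run edge", {
  # epochs: N2 N2 W W W N2 -> wake run [60, 150)
  st <- c("N2", "N2", "W", "W", "W", "N2")
  ar <- scored_events(
    type = rep("arousal_cortical", 5),
    onset = c(40, 70, 80, 140, 136),
    duration = rep(5, 5))
  kept <- filter_arousals(ar, st)
  # 40: sleep -> kept; 70: 10 s into wake run -> kept; 80: 20 s in, 70 s
  # from end -> dropped; 140: within last 15 s (>= 135) -> kept; 136: kept
  expect_setequal(kept$onset, c(40, 70, 140, 136))
})

test_that("hypopnea confirmation follows the desaturation and arousal window rules", {
  hyp <- scored_events("hypopnea", 100, 30)
  de_ok <- scored_events("desaturation", 140, 10, depth = 4)
  de_shallow <- scored_events("desaturation", 140, 10, depth = 2)
  de_late <- scored_events("desaturation", 190, 10, depth = 4)
  ar <- scored_events("arousal_autonomic", 131, 5)

  expect_equal(nrow(confirm_hypopneas(hyp, de_ok)), 1)
  expect_equal(nrow(confirm_hypopneas(hyp, de_shallow)), 0)
  expect_equal(nrow(confirm_hypopneas(hyp, de_late)), 0)  # 60 s > 45 s window
  expect_equal(nrow(confirm_hypopneas(hyp, de_shallow, ar,
                                      mode = "desat_or_arousal")), 1)
  expect_equal(nrow(confirm_hypopneas(hyp, de_shallow, ar,
                                      mode = "desat_only")), 0)
})

test_that("one desaturation cannot confirm two hypopneas (greedy one-to-one pairing)", {
  hyp <- scored_events(rep("hypopnea", 2), c(100, 150), c(20, 20))
  de <- scored_events("desaturation", 172, 10, depth = 5)
  conf <- confirm_hypopneas(hyp, de)
  expect_equal(nrow(conf), 1)
  expect_equal(conf$onset, 150)  # closer hypopnea end wins
})

test_that("index arithmetic matches the worked examples", {
  # 8 apneas + 2 desat-confirmed hypopneas in 2 h of recording, 1.6 h of
  # estimated sleep, all during sleep
  st_est <- c(rep("N2", 192), rep("W", 48))      # 1.6 h sleep of 2 h
  onsets <- seq(100, by = 500, length.out = 10)
  ev <- dplyr::bind_rows(
    scored_events(rep("apnea_obstructive", 8), onsets[1:8], 15),
    scored_events(rep("hypopnea", 2), onsets[9:10], 20),
    scored_events(rep("desaturation", 2), onsets[9:10] + 35, 10, depth = 4))
  est <- annotation_set(st_est, ev, 7200)
  ref <- annotation_set(rep("N2", 240), ev, 7200)
  rep_ <- compute_indices(ref, est)
  expect_equal(rep_$rei, 10 / 2)
  expect_equal(rep_$ahi_cress, 10 / 1.6)
  expect_equal(rep_$class_rei, "Mild")
  # zero events -> all indices 0
  ref0 <- annotation_set(rep("N2", 240), rec_duration = 7200)
  est0 <- annotation_set(st_est, rec_duration = 7200)
  rep0 <- compute_indices(ref0, est0)
  expect_equal(rep0$ahi_psg + rep0$rei + rep0$ahi_cress +
                 rep0$ahi_cress_autar + rep0$ari + rep0$autari, 0)
})

test_that("compute_indices agrees exactly with the brute-force oracle on random annotation sets", {
  rng <- local_rng(2024)
  for (i in 1:120) {
    ref <- random_annotations(rng, rec_duration = 3600)
    est <- random_annotations(rng, rec_duration = 3600)
    rep_ <- compute_indices(ref, est)
    o_psg <- oracle_counts(ref, "arousal_cortical", "desat_or_arousal")
    o_rei <- oracle_counts(
      annotation_set(rep("N2", length(est$stages)), est$events,
                     est$rec_duration),
      "arousal_autonomic", "desat_only")
    o_cress <- oracle_counts(est, "arousal_autonomic", "desat_only")
    o_autar <- oracle_counts(est, "arousal_autonomic", "desat_or_arousal")
    tst_ref <- 30 * sum(ref$stages != "W") / 3600
    tst_est <- 30 * sum(est$stages != "W") / 3600
    if (tst_ref > 0) {
      expect_equal(rep_$ahi_psg, o_psg$n_events / tst_ref, tolerance = 1e-12)
      expect_equal(rep_$ari, o_psg$n_arousals / tst_ref, tolerance = 1e-12)
    }
    expect_equal(rep_$rei, o_rei$n_events / 1, tolerance = 1e-12)
    if (tst_est > 0) {
      expect_equal(rep_$ahi_cress, o_cress$n_events / tst_est,
                   tolerance = 1e-12)
      expect_equal(rep_$ahi_cress_autar, o_autar$n_events / tst_est,
                   tolerance = 1e-12)
    }
    expect_gte(rep_$ahi_cress_autar, rep_$ahi_cress)
  }
})

test_that("with a perfect hypnogram and autonomic = cortical arousals the sleep-staged AHI equals the PSG AHI", {
  rng <- local_rng(77)
  for (i in 1:25) {
    ref <- random_annotations(rng, rec_duration = 3600)
    ev <- ref$events
    ar <- ev[ev$type == "arousal_cortical", , drop = FALSE]
    if (nrow(ar)) ar$type <- "arousal_autonomic"
    est <- annotation_set(ref$stages,
                          dplyr::bind_rows(
                            ev[ev$type != "arousal_cortical", , drop = FALSE],
                            ar),
                          ref$rec_duration)
    rep_ <- compute_indices(ref, est)
    expect_equal(rep_$ahi_cress_autar, rep_$ahi_psg, tolerance = 1e-12)
  }
})

test_that("severity classes use left-closed bins at 5, 15, 30", {
  expect_equal(severity_class(c(0, 4.99, 5, 14.99, 15, 29.99, 30, 80)),
               c("None", "None", "Mild", "Mild", "Moderate", "Moderate",
                 "Severe", "Severe"))
  expect_error(severity_class(-1))
})

test_that("undefined indices (countable events but zero sleep) raise an error", {
  # an arousal in the first 15 s of the (all-wake) recording survives the
  # wake filter, but there is no sleep time to divide by
  ev <- scored_events("arousal_cortical", 5, 5)
  ref <- annotation_set(rep("W", 2), ev, 60)
  est <- annotation_set(rep("N2", 2), rec_duration = 60)
  expect_error(compute_indices(ref, est), "undefined")
})
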