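test_that("hypnogram generation follows the configured Markov chain", {
  cfg <- cohort_config(rec_duration = 300 * 30, seed = 1)
  # identity transition matrix, start W -> all W (with a warning about the
  # absorbing wake state)
  cfg_id <- cfg
  cfg_id$transition <- diag(5)
  dimnames(cfg_id$transition) <- dimnames(cfg$transition)
  expect_warning(h <- gen_hypnogram(cfg_id), "absorbing")
  expect_true(all(h == "W"))

  # empirical transition frequencies within 3 SE of the chain
  cfg_big <- cohort_config(rec_duration = 10000 * 30, seed = 2)
  h <- gen_hypnogram(cfg_big)
  expect_equal(h[1], "W")
  tm <- cfg_big$transition
  from <- h[-length(h)]; to <- h[-1]
  for (s in rownames(tm)) {
    n_s <- sum(from == s)
    if (n_s < 50) next
    for (t in colnames(tm)) {
      p <- tm[s, t]
      se <- sqrt(p * (1 - p) / n_s)
      expect_lt(abs(mean(to[from == s] == t) - p), max(3 * se, 1e-9))
    }
  }
  # determinism
  expect_identical(gen_hypnogram(cfg_big), h)
})

test_that("event generation respects sleep placement and the Poisson rate", {
  cfg <- cohort_config(rec_duration = 8 * 3600, seed = 3)
  # no rates -> no events
  h <- gen_hypnogram(cfg)
  cfg0 <- cfg; cfg0$spontaneous_arousal_rate <- 0
  ev0 <- gen_events(h, cfg0, local_rng(1), event_rate = 0)
  expect_equal(nrow(ev0), 0)
  # all-wake hypnogram -> no respiratory events
  evw <- gen_events(rep("W", 960), cfg, local_rng(1))
  expect_equal(nrow(evw[evw$type %in% c("apnea_obstructive", "apnea_central",
                                        "apnea_mixed", "hypopnea"), ]), 0)
  # every event lies inside the recording; desaturation depths >= 3
  ev <- gen_events(h, cfg, local_rng(4))
  expect_true(all(ev$onset >= 0))
  expect_true(all(ev$onset + ev$duration <= cfg$rec_duration))
  resp <- ev[ev$type %in% c("apnea_obstructive", "apnea_central",
                            "apnea_mixed", "hypopnea"), ]
  expect_true(all(resp$duration >= 10 & resp$duration <= 60))
  # respiratory event onsets fall in sleep epochs
  expect_true(all(h[floor(resp$onset / 30) + 1] != "W"))

  # Poisson mean: ~6 h of sleep at rate 30/h over many seeds
  st <- rep(c("N2", "N2", "N2", "W"), 180)  # 3/4 sleep of 2160 epochs
  cfgp <- cohort_config(rec_duration = length(st) * 30, seed = 5)
  cfgp$spontaneous_arousal_rate <- 0
  sleep_h <- sum(st != "W") * 30 / 3600
  lam <- 30 * sleep_h
  rng <- local_rng(8)
  counts <- vapply(1:200, function(i) {
    ev <- gen_events(st, cfgp, rng, event_rate = 30)
    nrow(ev[ev$type %in% c("apnea_obstructive", "apnea_central",
                           "apnea_mixed", "hypopnea"), ])
  }, 0)
  se <- sqrt(lam / 200)
  # placement re-draws keep the realized count at the Poisson draw up to a
  # small residual from recordings too crowded to fit an event
  expect_lt(abs(mean(counts) - lam), 3 * se + 0.02 * lam)
})

test_that("IHR traces carry arousal surges of the configured shape", {
  cfg <- cohort_config(rec_duration = 300, seed = 6)
  # no arousals, no HRV noise -> constant baseline
  cfg0 <- cfg; cfg0$hrv_sd <- 0
  ihr0 <- gen_ihr(scored_events(), cfg0, local_rng(1), hr_baseline = 62)
  expect_true(all(abs(ihr0$samples - 62) < 1e-9))
  # single arousal at t = 100: peak inside [100, 110]
  ar <- scored_events("arousal_cortical", 100, 6)
  ihr1 <- gen_ihr(ar, cfg0, local_rng(1), hr_baseline = 62)
  tpk <- (which.max(ihr1$samples) - 1) / 2
  expect_gte(tpk, 100); expect_lte(tpk, 110)
  expect_equal(max(ihr1$samples) - 62, cfg$hr_surge, tolerance = 0.05)
  # two arousals 60 s apart -> two local maxima above baseline + surge/2
  ar2 <- scored_events(rep("arousal_cortical", 2), c(60, 120), 5)
  ihr2 <- gen_ihr(ar2, cfg0, local_rng(1), hr_baseline = 62)
  for (t0 in c(60, 120)) {
    seg <- ihr2$samples[(2 * t0):(2 * (t0 + 15))]
    expect_gt(max(seg), 62 + cfg$hr_surge / 2)
  }
})

test_that("PPG pulse trains encode the instantaneous heart rate", {
  count_peaks <- function(x) {
    n <- length(x)
    sum(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n] &
          x[2:(n - 1)] > 0.5)
  }
  peak_times <- function(w) {
    x <- w$samples; n <- length(x)
    idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n] &
                   x[2:(n - 1)] > 0.5) + 1
    idx / w$rate
  }
  # constant 60 bpm for 60 s -> 60 +/- 1 pulse peaks
  ihr60 <- waveform(rep(60, 120), 2, "ihr")
  ppg <- gen_ppg(ihr60, local_rng(2))
  expect_equal(ppg$rate, 100)
  expect_lte(abs(count_peaks(ppg$samples) - 60), 1)
  # constant 120 bpm -> mean peak interval 0.5 +/- 0.02 s
  ihr120 <- waveform(rep(120, 120), 2, "ihr")
  ppg2 <- gen_ppg(ihr120, local_rng(2))
  expect_equal(mean(diff(peak_times(ppg2))), 0.5, tolerance = 0.02 / 0.5)
  # ramp 50 -> 100 bpm: inter-peak intervals decrease monotonically
  ihr_ramp <- waveform(seq(50, 100, length.out = 240), 2, "ihr")
  ppg3 <- gen_ppg(ihr_ramp, local_rng(2))
  iv <- diff(peak_times(ppg3))
  expect_true(all(diff(iv) < 0.02))  # monotone up to sampling granularity
  expect_lt(mean(diff(iv)), 0)
})

test_that("flow amplitude drops during events and recovers outside", {
  cfg <- cohort_config(rec_duration = 600, seed = 11)
  # no events: envelope close to 1
  f0 <- gen_flow(scored_events(), cfg, local_rng(3))
  seg_rms <- function(w, a, b) {
    s <- w$samples[(a * w$rate):(b * w$rate)]
    sqrt(mean(s^2))
  }
  expect_equal(seg_rms(f0, 10, 590) / sqrt(0.5), 1, tolerance = 0.1)
  # apnea [100, 120): inside RMS < 0.15 x outside RMS
  ap <- scored_events("apnea_central", 100, 20)
  f1 <- gen_flow(ap, cfg, local_rng(3))
  expect_lt(seg_rms(f1, 104, 118), 0.15 * seg_rms(f1, 200, 400))
  # hypopnea: peak excursions reduced by >= 30% vs pre-event baseline
  hy <- scored_events("hypopnea", 300, 30)
  f2 <- gen_flow(hy, cfg, local_rng(3))
  pk_in <- max(abs(f2$samples[(304 * 10):(326 * 10)]))
  pk_pre <- max(abs(f2$samples[(250 * 10):(295 * 10)]))
  expect_lt(pk_in, 0.7 * pk_pre)
})

test_that("hypnogram corruption follows the confusion matrix", {
  st <- rep(c("W", "N1", "N2", "N3", "R"), each = 2000)
  idm <- diag(5); dimnames(idm) <- list(STAGE <- c("W", "N1", "N2", "N3", "R"),
                                        STAGE)
  expect_identical(corrupt_hypnogram(st, idm, local_rng(1)), st)
  # W -> sleep with probability 1 eliminates wake
  allsleep <- idm
  allsleep["W", ] <- c(0, 0, 1, 0, 0)
  expect_true(all(corrupt_hypnogram(st, allsleep, local_rng(1)) != "W" |
                    st != "W"))
  cfg <- cohort_config()
  cc <- corrupt_hypnogram(st, cfg$corruption, local_rng(2))
  for (s in rownames(cfg$corruption)) {
    n_s <- sum(st == s)
    for (t in colnames(cfg$corruption)) {
      p <- cfg$corruption[s, t]
      se <- sqrt(p * (1 - p) / n_s)
      expect_lt(abs(mean(cc[st == s] == t) - p), max(3 * se, 1e-9))
    }
  }
})

test_that("cohorts are reproducible from the seed and span the severity classes", {
  cfg <- cohort_config(n_subjects = 12, rec_duration = 2 * 3600, seed = 31,
                       waveforms = FALSE,
                       event_rate_mixture = c(2, 10, 22, 45))
  c1 <- gen_cohort(cfg)
  c2 <- gen_cohort(cfg)
  expect_identical(c1, c2)
  expect_equal(length(gen_cohort(cohort_config(n_subjects = 0,
                                               waveforms = FALSE))), 0)
  rep_ <- score_cohort(c1)
  expect_gte(length(unique(rep_$class_psg)), 3)
  expect_setequal(unique(vapply(c1, `[[`, "", "database")),
                  c("cohortA", "cohortB"))
  # generator self-recovery: configured rate is recovered from reference
  # annotations within sampling error
  rates <- vapply(c1, `[[`, 0, "true_event_rate")
  obs <- vapply(c1, function(s) {
    n <- sum(s$psg_ref$events$type %in%
               c("apnea_obstructive", "apnea_central", "apnea_mixed",
                 "hypopnea"))
    n / (total_sleep_time(s$psg_ref) / 3600)
  }, 0)
  expect_gt(cor(rates, obs), 0.95)
})

test_that("ground-truth invariants hold: arousal surges and flow reductions are present", {
  cfg <- cohort_config(n_subjects = 1, rec_duration = 1200, seed = 13)
  s <- gen_cohort(cfg)[[1]]
  ihr_t <- wf_times(s$ihr)
  base <- median(s$ihr$samples)
  ar <- s$hsat_est$events[s$hsat_est$events$type == "arousal_autonomic", ]
  for (i in seq_len(nrow(ar))) {
    win <- ihr_t >= ar$onset[i] - 5 & ihr_t <= ar$onset[i] + 5 + 10
    expect_gt(max(s$ihr$samples[win]) - base, cfg$hr_surge / 2 - cfg$hrv_sd)
  }
})
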