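#' Default cohort configuration for the synthetic generator
#'
#' The generator emulates overnight recordings with the structure the
#' scoring rules and the detector need: Markov-chain hypnograms on 30-s
#' epochs, respiratory events during sleep at a Poisson rate with
#' probabilistic desaturation and arousal consequences, arousal-linked
#' transient heart-rate accelerations rendered into a PPG pulse wave, and
#' flow-amplitude reductions during events. An estimated (HSAT-style)
#' annotation set is derived by corrupting the hypnogram with a per-epoch
#' confusion matrix and replacing cortical with coupled autonomic arousals.
#'
#' @param n_subjects Number of subjects.
#' @param rec_duration Recording duration in seconds (default 8 h).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param ... Overrides for any other field (see the returned list).
#' @return A list of generator parameters.
#' @export
cohort_config <- function(n_subjects = 20, rec_duration = 8 * 3600,
                          seed = 1L, ...) {
  trans <- matrix(c(
    # to:  W     N1    N2    N3    R        from:
    0.85, 0.12, 0.03, 0.00, 0.00,  # W
    0.10, 0.40, 0.45, 0.00, 0.05,  # N1
    0.03, 0.05, 0.80, 0.09, 0.03,  # N2
    0.02, 0.01, 0.12, 0.85, 0.00,  # N3
    0.05, 0.05, 0.05, 0.00, 0.85), # R
    5, 5, byrow = TRUE, dimnames = list(STAGE_LEVELS, STAGE_LEVELS))
  corr <- matrix(c(
    0.80, 0.12, 0.08, 0.00, 0.00,
    0.15, 0.55, 0.28, 0.00, 0.02,
    0.04, 0.08, 0.80, 0.06, 0.02,
    0.02, 0.02, 0.16, 0.80, 0.00,
    0.06, 0.04, 0.08, 0.00, 0.82),
    5, 5, byrow = TRUE, dimnames = list(STAGE_LEVELS, STAGE_LEVELS))
  cfg <- list(
    n_subjects = n_subjects,
    rec_duration = rec_duration,
    seed = seed,
    transition = trans,
    corruption = corr,
    event_rate = 15,            # respiratory events per sleep-hour
    event_rate_mixture = NULL,  # optional per-subject mixture (see gen_cohort)
    p_hypopnea = 0.5,           # fraction of respiratory events that are hypopneas
    apnea_subtype_p = c(apnea_obstructive = 0.6, apnea_central = 0.3,
                        apnea_mixed = 0.1),
    p_desat = 0.7,              # hypopnea followed by a >=3% desaturation
    p_arousal = 0.6,            # event terminates in a cortical arousal
    p_autonomic_given_cortical = 0.85,
    p_autonomic_spurious = 0.10,  # autonomic-only arousal per respiratory event
    spontaneous_arousal_rate = 10, # cortical arousals per sleep-hour
    hr_baseline = 65,           # bpm; per-subject jitter sd 6 bpm
    hr_baseline_sd = 6,
    hr_surge = 25,              # peak of the post-arousal tachycardia, bpm
    hrv_sd = 3,                 # smooth heart-rate variability, bpm
    breaths_per_min = c(12, 18),
    waveforms = TRUE            # set FALSE to skip PPG/flow/SpO2 rendering
  )
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  probs <- c(cfg$p_hypopnea, cfg$p_desat, cfg$p_arousal,
             cfg$p_autonomic_given_cortical, cfg$p_autonomic_spurious)
  stopifnot(all(probs >= 0 & probs <= 1),
            cfg$event_rate >= 0, cfg$spontaneous_arousal_rate >= 0,
            all(abs(rowSums(cfg$transition) - 1) < 1e-9),
            all(abs(rowSums(cfg$corruption) - 1) < 1e-9),
            all(cfg$transition >= 0), all(cfg$corruption >= 0))
  invisible(cfg)
}

#' Generate a hypnogram from the configured Markov chain
#'
#' The first epoch is wake; subsequent epochs follow the per-epoch stage
#' transition matrix.
#'
#' @param cfg Cohort configuration.
#' @param rng RNG stream from `local_rng()`; defaults to one from
#'   `cfg$seed`.
#' @return Character stage vector of length `ceiling(rec_duration / 30)`.
#' @export
gen_hypnogram <- function(cfg, rng = local_rng(cfg$seed)) {
  n <- ceiling(cfg$rec_duration / EPOCH_LEN)
  tm <- cfg$transition
  if (all(tm["W", c("N1", "N2", "N3", "R")] == 0)) {
    warning("wake is absorbing: the generated hypnogram contains no sleep")
  }
  stages <- character(n)
  stages[1] <- "W"
  # draw all uniforms in one call so the stream advances predictably
  u <- rng$runif(n - 1)
  cum <- t(apply(tm, 1, cumsum))
  for (i in seq_len(n - 1)) {
    stages[i + 1] <- STAGE_LEVELS[findInterval(u[i], cum[stages[i], ],
                                               left.open = TRUE) + 1]
  }
  stages
}

#' Generate scored events for a hypnogram
#'
#' Respiratory events (10-60 s) are placed with onsets in sleep epochs at a
#' Poisson rate per sleep-hour, and given probabilistic consequences:
#' hypopneas may be followed by a >=3% desaturation (lag 10-30 s, depth
#' 3-8%), any respiratory event may terminate in a cortical arousal, and
#' autonomic arousals are generated from cortical ones (coupling
#' probability) plus spurious autonomic-only arousals per respiratory event
#' (emulating, e.g., limb-movement-related discordance). Spontaneous
#' cortical arousals occur at their own rate per sleep-hour.
#'
#' @param stages Hypnogram stage vector.
#' @param cfg Cohort configuration.
#' @param rng RNG stream.
#' @param event_rate Optional override of `cfg$event_rate`.
#' @return Event tibble containing reference and estimate event types.
#' @export
gen_events <- function(stages, cfg, rng = local_rng(cfg$seed),
                       event_rate = cfg$event_rate) {
  rec_dur <- cfg$rec_duration
  sleep_epochs <- which(stages != "W")
  sleep_h <- length(sleep_epochs) * EPOCH_LEN / 3600
  ev <- list()

  if (length(sleep_epochs) > 0 && event_rate > 0) {
    n_resp <- rng$rpois(1, event_rate * sleep_h)
    if (n_resp > 0) {
      # sequential placement with re-draws on collision, so the realized
      # count stays at the Poisson draw while events never overlap
      duration <- rng$runif(n_resp, 10, 60)
      onset <- rep(NA_real_, n_resp)
      acc_on <- numeric(0); acc_off <- numeric(0)
      for (i in seq_len(n_resp)) {
        for (try in 1:25) {
          ep <- sleep_epochs[rng$sample(length(sleep_epochs), 1)]
          cand <- (ep - 1) * EPOCH_LEN + rng$runif(1, 0, EPOCH_LEN)
          if (cand + duration[i] > rec_dur) next
          if (!any(cand < acc_off & acc_on < cand + duration[i])) {
            onset[i] <- cand
            acc_on <- c(acc_on, cand)
            acc_off <- c(acc_off, cand + duration[i])
            break
          }
        }
      }
      keep <- !is.na(onset)
      onset <- onset[keep]; duration <- duration[keep]
      ord <- order(onset)
      onset <- onset[ord]; duration <- duration[ord]
      n <- length(onset)
      if (n > 0) {
        is_hyp <- rng$runif(n) < cfg$p_hypopnea
        cum_sub <- cumsum(cfg$apnea_subtype_p / sum(cfg$apnea_subtype_p))
        subtype <- names(cfg$apnea_subtype_p)[
          findInterval(rng$runif(n), cum_sub, left.open = TRUE) + 1]
        type <- ifelse(is_hyp, "hypopnea", subtype)
        ev$resp <- scored_events(type, onset, duration)

        # desaturations after hypopneas
        hyp_i <- which(is_hyp)
        gets_desat <- hyp_i[rng$runif(length(hyp_i)) < cfg$p_desat]
        if (length(gets_desat)) {
          lag <- rng$runif(length(gets_desat), 10, 30)
          d_on <- onset[gets_desat] + duration[gets_desat] + lag
          d_dur <- rng$runif(length(gets_desat), 10, 20)
          d_dep <- rng$runif(length(gets_desat), 3, 8)
          ok <- d_on + d_dur <= rec_dur
          if (any(ok)) {
            ev$desat <- scored_events("desaturation", d_on[ok], d_dur[ok],
                                      d_dep[ok])
          }
        }

        # event-terminating cortical arousals
        gets_ar <- which(rng$runif(n) < cfg$p_arousal)
        if (length(gets_ar)) {
          a_on <- onset[gets_ar] + duration[gets_ar]
          a_dur <- rng$runif(length(gets_ar), 3, 10)
          ok <- a_on + a_dur <= rec_dur
          if (any(ok)) {
            ev$resp_arousal <- scored_events("arousal_cortical", a_on[ok],
                                             a_dur[ok])
          }
        }

        # spurious autonomic-only arousals
        spur <- which(rng$runif(n) < cfg$p_autonomic_spurious)
        if (length(spur)) {
          s_on <- onset[spur] + duration[spur] + rng$runif(length(spur), 0, 2)
          s_dur <- rng$runif(length(spur), 3, 10)
          ok <- s_on + s_dur <= rec_dur
          if (any(ok)) {
            ev$spurious <- scored_events("arousal_autonomic", s_on[ok],
                                         s_dur[ok])
          }
        }
      }
    }
  }

  # spontaneous cortical arousals during sleep
  if (length(sleep_epochs) > 0 && cfg$spontaneous_arousal_rate > 0) {
    n_sp <- rng$rpois(1, cfg$spontaneous_arousal_rate * sleep_h)
    if (n_sp > 0) {
      ep <- sleep_epochs[rng$sample(length(sleep_epochs), n_sp,
                                    replace = TRUE)]
      s_on <- (ep - 1) * EPOCH_LEN + rng$runif(n_sp, 0, EPOCH_LEN)
      s_dur <- rng$runif(n_sp, 3, 10)
      ok <- s_on + s_dur <= rec_dur
      if (any(ok)) {
        ev$spont <- scored_events("arousal_cortical", s_on[ok], s_dur[ok])
      }
    }
  }

  out <- if (length(ev)) dplyr::bind_rows(ev) else scored_events()

  # autonomic arousals coupled to cortical arousals
  cort <- out[out$type == "arousal_cortical", , drop = FALSE]
  if (nrow(cort)) {
    coupled <- which(rng$runif(nrow(cort)) < cfg$p_autonomic_given_cortical)
    if (length(coupled)) {
      jitter <- rng$rnorm(length(coupled), 0, 0.5)
      a_on <- pmax(0, cort$onset[coupled] + jitter)
      a_dur <- cort$duration[coupled]
      ok <- a_on + a_dur <= rec_dur
      if (any(ok)) {
        out <- dplyr::bind_rows(out, scored_events("arousal_autonomic",
                                                   a_on[ok], a_dur[ok]))
      }
    }
  }
  out[order(out$onset, out$type), , drop = FALSE]
}

# linear-rise (2 s), exponential-decay (8 s time constant) surge kernel,
# peak normalized to 1
surge_kernel <- function(t, rise = 2, decay = 8) {
  ifelse(t < 0, 0, ifelse(t <= rise, t / rise, exp(-(t - rise) / decay)))
}

#' Generate a 2 Hz instantaneous-heart-rate trace
#'
#' Baseline plus smooth heart-rate-variability noise plus, for each arousal,
#' an additive tachycardia pulse (linear rise 2 s, exponential decay 8 s,
#' peak `hr_surge`). Arousal times closer than 3 s are merged so a coupled
#' cortical/autonomic pair produces a single surge.
#'
#' @param events Event tibble (arousal events drive surges).
#' @param cfg Cohort configuration.
#' @param rng RNG stream.
#' @param hr_baseline Baseline bpm (default drawn behaviour is handled in
#'   [gen_cohort()]; here the value is used as given).
#' @return A `waveform` at 2 Hz, values in bpm.
#' @export
gen_ihr <- function(events, cfg, rng = local_rng(cfg$seed),
                    hr_baseline = cfg$hr_baseline) {
  n <- ceiling(cfg$rec_duration * 2)
  t <- (seq_len(n) - 1) / 2
  ihr <- rep(hr_baseline, n)

  if (cfg$hrv_sd > 0) {
    white <- rng$rnorm(n)
    # gaussian smoothing (sd 2 s) then rescale to the configured sd
    kw <- 8
    kern <- stats::dnorm(seq(-3 * kw, 3 * kw), sd = kw)
    kern <- kern / sum(kern)
    sm <- stats::filter(c(rep(0, 3 * kw), white, rep(0, 3 * kw)), kern,
                        sides = 2)
    sm <- as.numeric(sm[(3 * kw + 1):(3 * kw + n)])
    sm[is.na(sm)] <- 0
    if (stats::sd(sm) > 0) ihr <- ihr + sm / stats::sd(sm) * cfg$hrv_sd
  }

  ar <- events[events$type %in% c("arousal_cortical", "arousal_autonomic"), ,
               drop = FALSE]
  if (nrow(ar)) {
    times <- sort(ar$onset)
    merged <- times[c(TRUE, diff(times) > 3)]
    for (a in merged) {
      idx <- which(t >= a & t <= a + 40)
      ihr[idx] <- ihr[idx] + cfg$hr_surge * surge_kernel(t[idx] - a)
    }
  }
  waveform(pmax(ihr, 31), rate = 2, label = "ihr")
}

#' Render a PPG waveform from an IHR trace
#'
#' Beat onset times are obtained by integrating `ihr/60`; each beat is
#' rendered as a fixed raised-cosine-squared pulse template with mild
#' amplitude jitter, so beat-to-beat intervals are recoverable from the
#' waveform by peak detection.
#'
#' @param ihr IHR `waveform` at 2 Hz (bpm, all > 30).
#' @param rng RNG stream.
#' @param rate Output sampling rate (100 Hz).
#' @return A `waveform` at `rate` Hz labelled `"ppg"`.
#' @export
gen_ppg <- function(ihr, rng = local_rng(1), rate = 100) {
  stopifnot(inherits(ihr, "waveform"), all(ihr$samples > 30))
  dur <- wf_duration(ihr)
  n <- round(dur * rate)
  tt <- (seq_len(n) - 1) / rate
  hz <- stats::approx(wf_times(ihr), ihr$samples / 60, xout = tt,
                      rule = 2)$y
  phase <- cumsum(hz) / rate
  beat_idx <- which(diff(floor(c(0, phase))) == 1)
  beats <- tt[beat_idx]
  ppg <- numeric(n)
  # pulse template: 0.45 s sin^2 lobe
  tpl_len <- round(0.45 * rate)
  tpl <- sin(pi * seq(0, 1, length.out = tpl_len))^2
  amp <- 1 + rng$rnorm(length(beats), 0, 0.05)
  for (b in seq_along(beats)) {
    i0 <- beat_idx[b]
    i1 <- min(n, i0 + tpl_len - 1)
    ppg[i0:i1] <- ppg[i0:i1] + amp[b] * tpl[seq_len(i1 - i0 + 1)]
  }
  waveform(ppg, rate, label = "ppg")
}

#' Render a respiratory flow waveform with event-related amplitude drops
#'
#' Sinusoid-like breathing at a per-subject rate (12-18 breaths/min) whose
#' amplitude envelope is multiplied by 0.05 during apneas and 0.4 during
#' hypopneas, with smooth (<= 2 s) transitions.
#'
#' @param events Event tibble (respiratory events shape the envelope).
#' @param cfg Cohort configuration.
#' @param rng RNG stream.
#' @param rate Output sampling rate (10 Hz).
#' @return A `waveform` labelled `"flow"`.
#' @export
gen_flow <- function(events, cfg, rng = local_rng(cfg$seed), rate = 10) {
  dur <- cfg$rec_duration
  n <- round(dur * rate)
  tt <- (seq_len(n) - 1) / rate
  bpm <- rng$runif(1, cfg$breaths_per_min[1], cfg$breaths_per_min[2])
  # slight breath-to-breath frequency wobble
  f <- bpm / 60 * (1 + 0.02 * sin(2 * pi * tt / 57))
  env <- rep(1, n)
  resp <- events[events$type %in% RESP_TYPES, , drop = FALSE]
  for (i in seq_len(nrow(resp))) {
    fac <- if (resp$type[i] == "hypopnea") 0.4 else 0.05
    idx <- tt >= resp$onset[i] & tt < resp$onset[i] + resp$duration[i]
    env[idx] <- fac
  }
  # 1.5 s moving-average ramp keeps transitions smooth
  k <- round(1.5 * rate)
  env <- stats::filter(c(rep(1, k), env, rep(1, k)), rep(1 / k, k), sides = 2)
  env <- as.numeric(env[(k + 1):(k + n)])
  env[is.na(env)] <- 1
  flow <- env * sin(2 * pi * cumsum(f) / rate) *
    (1 + 0.05 * sin(2 * pi * tt / 23))
  waveform(flow, rate, label = "flow")
}

# 1 Hz SpO2 channel: plateau at ~97% with dips at scored desaturations.
# Only the desaturation *annotations* are consumed downstream; the channel
# exists so synthetic recordings look like a complete HSAT montage.
gen_spo2 <- function(events, cfg) {
  n <- round(cfg$rec_duration)
  spo2 <- rep(97, n)
  de <- events[events$type == "desaturation", , drop = FALSE]
  tt <- seq_len(n) - 1
  for (i in seq_len(nrow(de))) {
    idx <- tt >= de$onset[i] & tt < de$onset[i] + de$duration[i]
    spo2[idx] <- 97 - de$depth[i]
  }
  waveform(spo2, 1, label = "spo2")
}

#' Corrupt a hypnogram with a per-epoch confusion matrix
#'
#' Emulates the error structure of cardio-respiratory sleep staging: each
#' epoch is independently relabelled according to the row of the confusion
#' matrix for its true stage.
#'
#' @param stages True hypnogram stage vector.
#' @param corruption 5x5 row-stochastic confusion matrix over W,N1,N2,N3,R.
#' @param rng RNG stream.
#' @return Corrupted stage vector of the same length.
#' @export
corrupt_hypnogram <- function(stages, corruption, rng = local_rng(1)) {
  stopifnot(all(abs(rowSums(corruption) - 1) < 1e-9))
  cum <- t(apply(corruption, 1, cumsum))
  u <- rng$runif(length(stages))
  vapply(seq_along(stages), function(i) {
    STAGE_LEVELS[findInterval(u[i], cum[stages[i], ], left.open = TRUE) + 1]
  }, "")
}

#' Generate a synthetic cohort
#'
#' Produces one subject record per subject: a reference annotation set
#' (true hypnogram, cortical arousals, respiratory events, desaturations),
#' an HSAT-style estimated annotation set (corrupted hypnogram, autonomic
#' arousals, the same respiratory events and desaturations), the true 2 Hz
#' IHR trace, and (optionally) PPG, flow and SpO2 waveforms. If
#' `cfg$event_rate_mixture` is a numeric vector of rates, each subject's
#' respiratory event rate is drawn uniformly from it, which spreads the
#' cohort across the four severity classes.
#'
#' @param cfg Cohort configuration from [cohort_config()].
#' @return A list of `subject_record` lists with elements `subject_id`,
#'   `database`, `psg_ref`, `hsat_est`, `ihr`, `waveforms`,
#'   `true_event_rate`.
#' @export
gen_cohort <- function(cfg) {
  validate_cohort_config(cfg)
  rng <- local_rng(cfg$seed)
  lapply(seq_len(cfg$n_subjects), function(s) {
    srng <- rng$spawn()
    rate <- if (!is.null(cfg$event_rate_mixture)) {
      mix <- cfg$event_rate_mixture
      mix[srng$sample(length(mix), 1)]
    } else cfg$event_rate
    hr0 <- cfg$hr_baseline + srng$rnorm(1, 0, cfg$hr_baseline_sd)
    stages <- gen_hypnogram(cfg, srng)
    events <- gen_events(stages, cfg, srng, event_rate = rate)
    ihr <- gen_ihr(events, cfg, srng, hr_baseline = hr0)
    waves <- NULL
    if (isTRUE(cfg$waveforms)) {
      waves <- list(ppg = gen_ppg(ihr, srng),
                    flow = gen_flow(events, cfg, srng),
                    spo2 = gen_spo2(events, cfg))
    }
    ref_types <- c("arousal_cortical", RESP_TYPES, "desaturation")
    est_types <- c("arousal_autonomic", RESP_TYPES, "desaturation")
    psg_ref <- annotation_set(stages,
                              events[events$type %in% ref_types, ],
                              cfg$rec_duration)
    est_stages <- corrupt_hypnogram(stages, cfg$corruption, srng)
    hsat_est <- annotation_set(est_stages,
                               events[events$type %in% est_types, ],
                               cfg$rec_duration)
    structure(list(subject_id = sprintf("S%03d", s),
                   database = if (s %% 2 == 1) "cohortA" else "cohortB",
                   psg_ref = psg_ref, hsat_est = hsat_est, ihr = ihr,
                   waveforms = waves, true_event_rate = rate),
              class = "subject_record")
  })
}
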