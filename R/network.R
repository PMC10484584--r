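#' Default architecture configuration for the arousal detector
#'
#' Three modules built from residual dilated-convolution blocks:
#' * a cardiac feature-extraction module (PPG at 100 Hz in, four blocks with
#'   temporal pooling 5-5-2-1 down to 2 Hz, then three time-distributed
#'   dense layers) trained to regress instantaneous heart rate (IHR);
#' * a respiratory module (flow at 10 Hz in, a single block pooling to
#'   2 Hz);
#' * an arousal module (three blocks without pooling plus two dense layers)
#'   that turns the combined features into an arousal probability at 2 Hz.
#'
#' By default the cardiac information reaching the arousal module is the
#' single 2 Hz IHR value (`wiring = "ihr"`), which keeps the detector
#' agnostic to the cardiac sensor; `wiring = "features"` feeds the cardiac
#' head's penultimate features instead. Channel widths, kernel size and
#' dilation schedules are configurable; the defaults give a total receptive
#' field of about 85 s (roughly +/- 43 s of temporal context).
#'
#' @param ... Overrides for any configuration field.
#' @return A `model_config` list.
#' @export
model_config <- function(...) {
  cfg <- list(
    cardiac = list(
      in_rate = 100,
      channels = c(8, 12, 16, 16),
      pool = c(5, 5, 2, 1),
      dilations = list(c(1, 2, 4, 8), c(1, 2, 4, 8), c(1, 2, 4, 8),
                       c(1, 2, 4, 8)),
      kernel = 3,
      head = c(16, 8, 1)
    ),
    resp = list(
      in_rate = 10,
      channels = 8,
      pool = 5,
      dilations = list(c(1, 2, 4, 8)),
      kernel = 3
    ),
    arousal = list(
      channels = c(16, 16, 16),
      pool = c(1, 1, 1),
      dilations = list(c(1, 2, 4, 8, 16), c(1, 2, 4, 8), c(1, 2, 4, 8)),
      kernel = 3,
      head = c(8, 1)
    ),
    out_rate = 2,
    wiring = "ihr",
    ihr_center = 60,   # bpm; network regresses (ihr - center) / scale
    ihr_scale = 30
  )
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg <- utils::modifyList(cfg, over)
  cfg
}

#' Total receptive field of a configuration, in seconds
#'
#' Sum over all convolution layers of `dilation * (kernel - 1)` sample
#' spacings at each layer's operating rate, over the (serial) cardiac and
#' arousal paths.
#'
#' @param cfg A `model_config`.
#' @return Receptive field in seconds (total width, both sides).
#' @export
receptive_field_seconds <- function(cfg) {
  half <- 0
  r <- cfg$cardiac$in_rate
  for (i in seq_along(cfg$cardiac$channels)) {
    half <- half + sum(cfg$cardiac$dilations[[i]]) *
      (cfg$cardiac$kernel - 1) / 2 / r
    r <- r / cfg$cardiac$pool[i]
  }
  for (i in seq_along(cfg$arousal$channels)) {
    half <- half + sum(cfg$arousal$dilations[[i]]) *
      (cfg$arousal$kernel - 1) / 2 / cfg$out_rate
  }
  2 * half
}

#' Build (initialize) an arousal detection model
#'
#' @param cfg A `model_config`.
#' @param seed Integer seed for weight initialization.
#' @return An `arousal_model` with untrained parameters.
#' @export
build_model <- function(cfg = model_config(), seed = 1L) {
  if (cfg$cardiac$in_rate / prod(cfg$cardiac$pool) != cfg$out_rate) {
    stop("cardiac pooling does not map ", cfg$cardiac$in_rate,
         " Hz to ", cfg$out_rate, " Hz")
  }
  if (cfg$resp$in_rate / prod(cfg$resp$pool) != cfg$out_rate) {
    stop("respiratory pooling does not map ", cfg$resp$in_rate,
         " Hz to ", cfg$out_rate, " Hz")
  }
  if (any(cfg$arousal$pool != 1)) {
    stop("the arousal module must not pool temporally")
  }
  if (cfg$cardiac$kernel %% 2 != 1) stop("kernel size must be odd")
  rf <- receptive_field_seconds(cfg)
  if (rf < 80 || rf > 100) {
    warning(sprintf("receptive field %.1f s outside the targeted 80-100 s",
                    rf))
  }
  rng <- local_rng(seed)
  cc <- cfg$cardiac
  cardiac <- list(blocks = list(), head = list())
  cin <- 1
  for (i in seq_along(cc$channels)) {
    cardiac$blocks[[i]] <- block_init(cin, cc$channels[i], cc$dilations[[i]],
                                      cc$kernel, rng)
    cin <- cc$channels[i]
  }
  for (i in seq_along(cc$head)) {
    cardiac$head[[i]] <- dense_init(cin, cc$head[i], rng)
    cin <- cc$head[i]
  }
  rc <- cfg$resp
  resp <- list(blocks = list())
  cin <- 1
  for (i in seq_along(rc$channels)) {
    resp$blocks[[i]] <- block_init(cin, rc$channels[i], rc$dilations[[i]],
                                   rc$kernel, rng)
    cin <- rc$channels[i]
  }
  ac <- cfg$arousal
  n_cardiac_feat <- if (cfg$wiring == "ihr") 1 else {
    cc$head[length(cc$head) - 1]
  }
  arousal <- list(blocks = list(), head = list())
  cin <- n_cardiac_feat + rc$channels[length(rc$channels)]
  for (i in seq_along(ac$channels)) {
    arousal$blocks[[i]] <- block_init(cin, ac$channels[i], ac$dilations[[i]],
                                      ac$kernel, rng)
    cin <- ac$channels[i]
  }
  for (i in seq_along(ac$head)) {
    arousal$head[[i]] <- dense_init(cin, ac$head[i], rng)
    cin <- ac$head[i]
  }
  structure(list(cfg = cfg,
                 params = list(cardiac = cardiac, resp = resp,
                               arousal = arousal),
                 trained = character()),
            class = "arousal_model")
}

#' @export
print.arousal_model <- function(x, ...) {
  np <- sum(unlist(tree_map(length, x$params)))
  cat(sprintf("<arousal_model> %d parameters, receptive field %.1f s, trained: %s\n",
              np, receptive_field_seconds(x$cfg),
              if (length(x$trained)) paste(x$trained, collapse = "+") else "no"))
  invisible(x)
}

# ---- forward / backward passes ------------------------------------------

forward_cardiac <- function(mp, cfg, X, keep = FALSE) {
  cc <- cfg$cardiac
  H <- X
  bc <- vector("list", length(cc$channels))
  for (i in seq_along(cc$channels)) {
    r <- block_fwd(H, mp$blocks[[i]], cc$dilations[[i]], cc$pool[i])
    bc[[i]] <- r$cache
    H <- r$Y
  }
  feat <- H
  z1 <- dense_fwd(feat, mp$head[[1]]); a1 <- z1 * (z1 > 0)
  z2 <- dense_fwd(a1, mp$head[[2]]); a2 <- z2 * (z2 > 0)
  y <- dense_fwd(a2, mp$head[[3]])
  out <- list(ihr_norm = y, penult = a2)
  if (keep) {
    out$cache <- list(blocks = bc, feat = feat, z1 = z1, a1 = a1,
                      z2 = z2, a2 = a2)
  }
  out
}

backward_cardiac <- function(mp, cfg, cache, dY) {
  cc <- cfg$cardiac
  g <- list(blocks = vector("list", length(cc$channels)),
            head = vector("list", 3))
  d3 <- dense_bwd(cache$a2, mp$head[[3]], dY)
  g$head[[3]] <- d3$grad
  dz2 <- d3$dX * (cache$z2 > 0)
  d2 <- dense_bwd(cache$a1, mp$head[[2]], dz2)
  g$head[[2]] <- d2$grad
  dz1 <- d2$dX * (cache$z1 > 0)
  d1 <- dense_bwd(cache$feat, mp$head[[1]], dz1)
  g$head[[1]] <- d1$grad
  dH <- d1$dX
  for (i in rev(seq_along(cc$channels))) {
    bb <- block_bwd(mp$blocks[[i]], cc$dilations[[i]], cc$pool[i],
                    cache$blocks[[i]], dH)
    g$blocks[[i]] <- bb$grad
    dH <- bb$dX
  }
  g
}

forward_resp <- function(mp, cfg, X, keep = FALSE) {
  rc <- cfg$resp
  H <- X
  bc <- vector("list", length(rc$channels))
  for (i in seq_along(rc$channels)) {
    r <- block_fwd(H, mp$blocks[[i]], rc$dilations[[i]], rc$pool[i])
    bc[[i]] <- r$cache
    H <- r$Y
  }
  out <- list(feat = H)
  if (keep) out$cache <- list(blocks = bc)
  out
}

backward_resp <- function(mp, cfg, cache, dY) {
  rc <- cfg$resp
  g <- list(blocks = vector("list", length(rc$channels)))
  dH <- dY
  for (i in rev(seq_along(rc$channels))) {
    bb <- block_bwd(mp$blocks[[i]], rc$dilations[[i]], rc$pool[i],
                    cache$blocks[[i]], dH)
    g$blocks[[i]] <- bb$grad
    dH <- bb$dX
  }
  g
}

forward_arousal <- function(mp, cfg, A0, keep = FALSE) {
  ac <- cfg$arousal
  H <- A0
  bc <- vector("list", length(ac$channels))
  for (i in seq_along(ac$channels)) {
    r <- block_fwd(H, mp$blocks[[i]], ac$dilations[[i]], ac$pool[i])
    bc[[i]] <- r$cache
    H <- r$Y
  }
  z1 <- dense_fwd(H, mp$head[[1]]); a1 <- z1 * (z1 > 0)
  logits <- dense_fwd(a1, mp$head[[2]])
  out <- list(logits = logits, prob = 1 / (1 + exp(-logits)))
  if (keep) out$cache <- list(blocks = bc, feat = H, z1 = z1, a1 = a1)
  out
}

backward_arousal <- function(mp, cfg, cache, dlogits) {
  ac <- cfg$arousal
  g <- list(blocks = vector("list", length(ac$channels)),
            head = vector("list", 2))
  d2 <- dense_bwd(cache$a1, mp$head[[2]], dlogits)
  g$head[[2]] <- d2$grad
  dz1 <- d2$dX * (cache$z1 > 0)
  d1 <- dense_bwd(cache$feat, mp$head[[1]], dz1)
  g$head[[1]] <- d1$grad
  dH <- d1$dX
  for (i in rev(seq_along(ac$channels))) {
    bb <- block_bwd(mp$blocks[[i]], ac$dilations[[i]], ac$pool[i],
                    cache$blocks[[i]], dH)
    g$blocks[[i]] <- bb$grad
    dH <- bb$dX
  }
  list(grad = g, dX = dH)
}

# standardize a raw signal segment for network input
std_input <- function(x) {
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s < 1e-9) s <- 1
  matrix(x / s, nrow = 1)
}

#' Run the detector on a PPG/flow pair
#'
#' Inputs are (optionally) preprocessed, trimmed to their common time
#' interval, standardized and passed through the network. Deterministic:
#' the same model and inputs always give the same output.
#'
#' @param model A trained `arousal_model`.
#' @param ppg PPG `waveform`.
#' @param flow Respiratory flow `waveform`.
#' @param preprocess Apply [preprocess_ppg()] / [preprocess_flow()] first
#'   (default TRUE); set FALSE if the inputs are already at 100 / 10 Hz and
#'   high-pass filtered.
#' @return A list with `prob` (a `probability_series` at 2 Hz) and `ihr`
#'   (a 2 Hz `waveform` in bpm).
#' @export
predict_arousal <- function(model, ppg, flow, preprocess = TRUE) {
  stopifnot(inherits(model, "arousal_model"))
  if (preprocess) {
    ppg <- preprocess_ppg(ppg)
    flow <- preprocess_flow(flow)
  }
  if (ppg$rate != model$cfg$cardiac$in_rate ||
      flow$rate != model$cfg$resp$in_rate) {
    stop("input rates must be ", model$cfg$cardiac$in_rate, " Hz (PPG) and ",
         model$cfg$resp$in_rate, " Hz (flow)")
  }
  t0 <- max(ppg$start, flow$start)
  t1 <- min(ppg$start + wf_duration(ppg), flow$start + wf_duration(flow))
  n2 <- floor((t1 - t0) * model$cfg$out_rate)
  if (n2 < 1) stop("waveforms share no common interval")
  ppg_n <- n2 * model$cfg$cardiac$in_rate / model$cfg$out_rate
  flow_n <- n2 * model$cfg$resp$in_rate / model$cfg$out_rate
  pi0 <- round((t0 - ppg$start) * ppg$rate)
  fi0 <- round((t0 - flow$start) * flow$rate)
  xp <- std_input(ppg$samples[pi0 + seq_len(ppg_n)])
  xf <- std_input(flow$samples[fi0 + seq_len(flow_n)])
  fc <- forward_cardiac(model$params$cardiac, model$cfg, xp)
  fr <- forward_resp(model$params$resp, model$cfg, xf)
  cfeat <- if (model$cfg$wiring == "ihr") fc$ihr_norm else fc$penult
  fa <- forward_arousal(model$params$arousal, model$cfg,
                        rbind(cfeat, fr$feat))
  ihr_bpm <- model$cfg$ihr_center +
    model$cfg$ihr_scale * as.numeric(fc$ihr_norm)
  list(prob = probability_series(as.numeric(fa$prob), start = t0),
       ihr = waveform(pmax(ihr_bpm, 1), 2, label = "ihr_pred", start = t0))
}

#' Predict the IHR trace only (cardiac module)
#'
#' @param model An `arousal_model`.
#' @param ppg PPG `waveform` (preprocessed or raw, see `preprocess`).
#' @param preprocess Apply [preprocess_ppg()] first.
#' @return A 2 Hz `waveform` in bpm.
#' @export
predict_ihr <- function(model, ppg, preprocess = TRUE) {
  if (preprocess) ppg <- preprocess_ppg(ppg)
  rate <- model$cfg$cardiac$in_rate
  n2 <- floor(wf_duration(ppg) * model$cfg$out_rate)
  xp <- std_input(ppg$samples[seq_len(n2 * rate / model$cfg$out_rate)])
  fc <- forward_cardiac(model$params$cardiac, model$cfg, xp)
  bpm <- model$cfg$ihr_center + model$cfg$ihr_scale * as.numeric(fc$ihr_norm)
  waveform(pmax(bpm, 1), 2, label = "ihr_pred", start = ppg$start)
}

# temporal stretch augmentation: the window covers `window / f` source
# seconds starting at t0, resampled to `window` seconds; the apparent heart
# rate is the true IHR divided by f (a squeezed recording beats faster)
stretch_window <- function(ppg, ihr, t0, f, window, in_rate = 100,
                           out_rate = 2) {
  n_in <- window * in_rate
  n_out <- window * out_rate
  src_in <- t0 + (seq_len(n_in) - 1) / (in_rate * f)
  x <- stats::approx(seq(0, by = 1 / in_rate, length.out = length(ppg)),
                     ppg, xout = src_in, rule = 2)$y
  src_out <- t0 + (seq_len(n_out) - 1) / (out_rate * f)
  tgt <- stats::approx(seq(0, by = 1 / out_rate, length.out = length(ihr)),
                       ihr, xout = src_out, rule = 2)$y / f
  list(x = x, target = tgt)
}

# binary 2 Hz label sequence from arousal annotations
labels_2hz <- function(events, n2, types = "arousal_cortical") {
  lab <- numeric(n2)
  ar <- events[events$type %in% types, , drop = FALSE]
  t <- (seq_len(n2) - 1) / 2
  for (i in seq_len(nrow(ar))) {
    lab[t >= ar$onset[i] & t < ar$onset[i] + ar$duration[i]] <- 1
  }
  lab
}

#' Training configuration
#'
#' @param phase `"cardiac"` or `"end2end"`.
#' @param lr Adam learning rate.
#' @param iters Number of optimization steps.
#' @param batch Windows per step (gradients are averaged).
#' @param window Window length in seconds.
#' @param stretch Half-width of the temporal stretch augmentation range
#'   (cardiac phase): stretch factors are drawn uniformly from
#'   `[1 - stretch, 1 + stretch]` and IHR targets rescaled by the
#'   reciprocal factor.
#' @param pos_weight Positive-class weight in the arousal cross-entropy.
#' @param seed RNG seed; fixed seed implies a bit-identical training run.
#' @return A `train_config` list.
#' @export
train_config <- function(phase = c("cardiac", "end2end"), lr = 2e-3,
                         iters = 300, batch = 2, window = 240,
                         stretch = 0.2, pos_weight = 5, seed = 1L) {
  phase <- match.arg(phase)
  stopifnot(stretch >= 0, stretch < 1)
  list(phase = phase, lr = lr, iters = iters, batch = batch, window = window,
       stretch = stretch, pos_weight = pos_weight, seed = seed)
}

#' Train the cardiac module (IHR regression)
#'
#' The cardiac feature-extraction module is trained on its own, against the
#' ground-truth 2 Hz IHR traces, with temporal stretch augmentation: a
#' random stretch factor `f` is drawn per window, the input covers
#' `window / f` seconds resampled to `window` seconds, and the IHR target is
#' divided by `f` (a squeezed recording appears to beat faster). Loss is
#' mean absolute error on the normalized IHR.
#'
#' @param model An `arousal_model`.
#' @param cohort List of `subject_record`s with `waveforms$ppg` and `ihr`.
#' @param tc A `train_config` with `phase = "cardiac"`.
#' @return The model with a trained cardiac module plus a `log` attribute
#'   (tibble of iteration losses).
#' @export
train_cardiac <- function(model, cohort, tc = train_config("cardiac")) {
  stopifnot(tc$phase == "cardiac", length(cohort) >= 1)
  has_sleep <- vapply(cohort, function(s) {
    any(s$psg_ref$stages != "W")
  }, TRUE)
  if (!any(has_sleep)) stop("no sleep-period data to train on")
  rng <- local_rng(tc$seed)
  prep <- lapply(cohort, function(s) {
    ppg <- preprocess_ppg(s$waveforms$ppg)
    list(ppg = as.numeric(std_input(ppg$samples)), ihr = s$ihr$samples,
         dur = wf_duration(ppg))
  })
  cfg <- model$cfg
  rate <- cfg$cardiac$in_rate
  state <- adam_init(model$params$cardiac)
  losses <- numeric(tc$iters)
  for (it in seq_len(tc$iters)) {
    gacc <- NULL
    lsum <- 0
    for (b in seq_len(tc$batch)) {
      s <- rng$sample(length(prep), 1)
      f <- rng$runif(1, 1 - tc$stretch, 1 + tc$stretch)
      src_dur <- tc$window / f
      t0 <- rng$runif(1, 0, max(0.001, prep[[s]]$dur - src_dur))
      sw <- stretch_window(prep[[s]]$ppg, prep[[s]]$ihr, t0, f, tc$window,
                           in_rate = rate, out_rate = cfg$out_rate)
      tgt <- (sw$target - cfg$ihr_center) / cfg$ihr_scale
      fc <- forward_cardiac(model$params$cardiac, cfg, matrix(sw$x, 1),
                            keep = TRUE)
      resid <- as.numeric(fc$ihr_norm) - tgt
      lsum <- lsum + mean(abs(resid))
      dY <- matrix(sign(resid) / length(resid), 1) / tc$batch
      g <- backward_cardiac(model$params$cardiac, cfg, fc$cache, dY)
      gacc <- if (is.null(gacc)) g else tree_add(gacc, g)
    }
    st <- adam_step(model$params$cardiac, gacc, state, tc$lr)
    model$params$cardiac <- st$params
    state <- st$state
    losses[it] <- lsum / tc$batch
  }
  model$trained <- union(model$trained, "cardiac")
  attr(model, "log") <- tibble::tibble(iter = seq_len(tc$iters),
                                       loss = losses)
  model
}

#' Train the full model end-to-end with the cardiac module frozen
#'
#' Targets are 2 Hz binary sequences marking cortical-arousal samples in the
#' reference annotations; the loss is (positively weighted) binary
#' cross-entropy. The cardiac module's parameters are fixed: only the
#' respiratory and arousal modules receive gradient updates, and because the
#' cardiac module is frozen its 2 Hz output is precomputed once per subject.
#'
#' @param model An `arousal_model` whose cardiac module has been trained.
#' @param cohort List of `subject_record`s.
#' @param tc A `train_config` with `phase = "end2end"`.
#' @return The model with trained respiratory/arousal modules and a `log`
#'   attribute.
#' @export
train_end2end <- function(model, cohort, tc = train_config("end2end")) {
  stopifnot(tc$phase == "end2end")
  if (!"cardiac" %in% model$trained) {
    warning("cardiac module has not been trained; freezing random weights")
  }
  n_lab <- vapply(cohort, function(s) {
    sum(s$psg_ref$events$type == "arousal_cortical")
  }, 0L)
  if (sum(n_lab) == 0) stop("cohort contains no cortical arousal labels")
  rng <- local_rng(tc$seed)
  cfg <- model$cfg
  prep <- lapply(cohort, function(s) {
    ppg <- preprocess_ppg(s$waveforms$ppg)
    flow <- preprocess_flow(s$waveforms$flow)
    n2 <- floor(min(wf_duration(ppg), wf_duration(flow)) * cfg$out_rate)
    xp <- std_input(ppg$samples[seq_len(n2 * cfg$cardiac$in_rate / cfg$out_rate)])
    fc <- forward_cardiac(model$params$cardiac, cfg, xp)
    cfeat <- if (cfg$wiring == "ihr") fc$ihr_norm else fc$penult
    list(flow = as.numeric(std_input(
           flow$samples[seq_len(n2 * cfg$resp$in_rate / cfg$out_rate)])),
         cfeat = cfeat,
         labels = labels_2hz(s$psg_ref$events, n2),
         n2 = n2)
  })
  state <- adam_init(list(resp = model$params$resp,
                          arousal = model$params$arousal))
  losses <- numeric(tc$iters)
  n2w <- tc$window * cfg$out_rate
  n10w <- tc$window * cfg$resp$in_rate
  for (it in seq_len(tc$iters)) {
    gacc <- NULL
    lsum <- 0
    for (b in seq_len(tc$batch)) {
      s <- rng$sample(length(prep), 1)
      max0 <- prep[[s]]$n2 - n2w
      j0 <- if (max0 > 0) rng$sample(max0 + 1, 1) - 1 else 0
      xf <- matrix(prep[[s]]$flow[j0 * 5 + seq_len(n10w)], 1)
      cf <- prep[[s]]$cfeat[, j0 + seq_len(n2w), drop = FALSE]
      lab <- prep[[s]]$labels[j0 + seq_len(n2w)]
      fr <- forward_resp(model$params$resp, cfg, xf, keep = TRUE)
      A0 <- rbind(cf, fr$feat)
      fa <- forward_arousal(model$params$arousal, cfg, A0, keep = TRUE)
      p <- as.numeric(fa$prob)
      w <- ifelse(lab == 1, tc$pos_weight, 1)
      eps <- 1e-12
      lsum <- lsum + mean(w * -(lab * log(p + eps) +
                                  (1 - lab) * log(1 - p + eps)))
      dlogits <- matrix(w * (p - lab) / length(lab), 1) / tc$batch
      ba <- backward_arousal(model$params$arousal, cfg, fa$cache, dlogits)
      dFr <- ba$dX[-seq_len(nrow(cf)), , drop = FALSE]
      gr <- backward_resp(model$params$resp, cfg, fr$cache, dFr)
      g <- list(resp = gr, arousal = ba$grad)
      gacc <- if (is.null(gacc)) g else tree_add(gacc, g)
    }
    st <- adam_step(list(resp = model$params$resp,
                         arousal = model$params$arousal),
                    gacc, state, tc$lr)
    model$params$resp <- st$params$resp
    model$params$arousal <- st$params$arousal
    state <- st$state
    losses[it] <- lsum / tc$batch
  }
  model$trained <- union(model$trained, "end2end")
  attr(model, "log") <- tibble::tibble(iter = seq_len(tc$iters),
                                       loss = losses)
  model
}

#' Hash of the cardiac module parameters
#'
#' Used to verify the freeze contract: end-to-end training must leave the
#' cardiac module bit-identical.
#'
#' @param model An `arousal_model`.
#' @return A character hash.
#' @export
cardiac_hash <- function(model) rlang::hash(model$params$cardiac)

#' Held-out IHR mean absolute error
#'
#' @param model An `arousal_model`.
#' @param cohort List of `subject_record`s with ground-truth IHR.
#' @return MAE in bpm, averaged over subjects.
#' @export
ihr_mae <- function(model, cohort) {
  errs <- vapply(cohort, function(s) {
    pred <- predict_ihr(model, s$waveforms$ppg)
    n <- min(length(pred$samples), length(s$ihr$samples))
    mean(abs(pred$samples[seq_len(n)] - s$ihr$samples[seq_len(n)]))
  }, numeric(1))
  mean(errs)
}
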