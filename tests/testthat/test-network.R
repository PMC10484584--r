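test_that("high-pass preprocessing attenuates drift and passes the signal band", {
  tt <- (0:29999) / 100
  # 0.05 Hz drift on the PPG path: attenuated by at least 20 dB
  slow <- waveform(sin(2 * pi * 0.05 * tt), 100, "ppg")
  out <- preprocess_ppg(slow)
  expect_lt(sqrt(mean(out$samples^2)), 0.1 * sqrt(0.5))
  # 1 Hz pulse band preserved within 5%
  pulse <- waveform(sin(2 * pi * 1 * tt), 100, "ppg")
  outp <- preprocess_ppg(pulse)
  expect_equal(sqrt(mean(outp$samples^2)), sqrt(0.5), tolerance = 0.05)
  # constant -> zeros
  cst <- preprocess_ppg(waveform(rep(3, 2000), 100, "ppg"))
  expect_lt(max(abs(cst$samples)), 1e-6)
  # flow: 0.25 Hz breathing preserved, 0.005 Hz drift removed
  tf <- (0:19999) / 10
  br <- preprocess_flow(waveform(sin(2 * pi * 0.25 * tf), 10, "flow"))
  expect_equal(sqrt(mean(br$samples^2)), sqrt(0.5), tolerance = 0.05)
  dr <- preprocess_flow(waveform(sin(2 * pi * 0.005 * tf), 10, "flow"))
  expect_lt(sqrt(mean(dr$samples^2)), 0.1 * sqrt(0.5))
  # resampling: a 50 Hz input is brought to 100 Hz
  w50 <- waveform(sin(2 * pi * 1 * (0:499) / 50), 50, "ppg")
  expect_equal(preprocess_ppg(w50)$rate, 100)
  expect_error(preprocess_ppg(waveform(numeric(0), 100)), "empty")
})

test_that("model construction validates rate arithmetic and emits 2 Hz outputs in [0, 1]", {
  m <- build_model(model_config(), seed = 1)
  expect_equal(receptive_field_seconds(m$cfg), 85.3, tolerance = 0.01)
  # bad pooling rejected
  bad <- model_config()
  bad$cardiac$pool <- c(5, 5, 2, 2)
  expect_error(build_model(bad), "does not map")
  bad2 <- model_config()
  bad2$arousal$pool <- c(2, 1, 1)
  expect_error(build_model(bad2), "must not pool")

  # 90 s of input -> 180 probability samples, all in [0, 1]
  rng <- local_rng(2)
  ppg <- waveform(rng$rnorm(9000), 100, "ppg")
  flow <- waveform(rng$rnorm(900), 10, "flow")
  out <- predict_arousal(m, ppg, flow, preprocess = FALSE)
  expect_equal(length(out$prob$values), 180)
  expect_true(all(out$prob$values >= 0 & out$prob$values <= 1))
  expect_equal(length(out$ihr$samples), 180)
  # determinism
  out2 <- predict_arousal(m, ppg, flow, preprocess = FALSE)
  expect_identical(out$prob$values, out2$prob$values)
  # rate mismatch and empty overlap are rejected
  expect_error(predict_arousal(m, waveform(rng$rnorm(900), 10), flow,
                               preprocess = FALSE), "rates")
  late <- waveform(rng$rnorm(900), 10, "flow", start = 1000)
  expect_error(predict_arousal(m, ppg, late, preprocess = FALSE),
               "common interval")
})

test_that("the receptive field is local: distant perturbations do not reach the output", {
  m <- build_model(model_config(), seed = 3)
  rng <- local_rng(4)
  dur <- 200
  xp <- matrix(rng$rnorm(dur * 100), 1)
  xf <- matrix(rng$rnorm(dur * 10), 1)
  fwd <- function(xp, xf) {
    fc <- hsatscore:::forward_cardiac(m$params$cardiac, m$cfg, xp)
    fr <- hsatscore:::forward_resp(m$params$resp, m$cfg, xf)
    fa <- hsatscore:::forward_arousal(m$params$arousal, m$cfg,
                                      rbind(fc$ihr_norm, fr$feat))
    as.numeric(fa$logits)
  }
  base <- fwd(xp, xf)
  mid <- length(base) / 2          # output sample at t = 100 s
  t_mid <- mid / 2
  # perturb PPG and flow everywhere farther than 50 s from t_mid
  xp2 <- xp; xf2 <- xf
  tp <- (seq_len(ncol(xp)) - 1) / 100
  tf <- (seq_len(ncol(xf)) - 1) / 10
  xp2[1, abs(tp - t_mid) > 50] <- xp2[1, abs(tp - t_mid) > 50] + 5
  xf2[1, abs(tf - t_mid) > 50] <- xf2[1, abs(tf - t_mid) > 50] - 5
  pert <- fwd(xp2, xf2)
  expect_lt(abs(pert[mid] - base[mid]), 1e-6)
  # ... but a perturbation inside the receptive field does reach it
  xp3 <- xp
  xp3[1, abs(tp - t_mid) < 10] <- xp3[1, abs(tp - t_mid) < 10] + 5
  expect_gt(abs(fwd(xp3, xf)[mid] - base[mid]), 1e-9)
})

test_that("temporal stretch augmentation rescales the IHR target by the reciprocal factor", {
  ppg <- sin(2 * pi * (0:99999) / 100)   # 1000 s at 100 Hz
  ihr <- rep(60, 2000)                   # constant 60 bpm at 2 Hz
  # factor 1: identity
  sw1 <- hsatscore:::stretch_window(ppg, ihr, 100, 1, 60)
  expect_equal(sw1$x, ppg[10001:16000], tolerance = 1e-9)
  expect_equal(sw1$target, rep(60, 120))
  # factor 0.8: a 60 bpm segment becomes 75 bpm
  sw <- hsatscore:::stretch_window(ppg, ihr, 100, 0.8, 60)
  expect_equal(sw$target, rep(75, 120))
  expect_equal(length(sw$x), 6000)
})

test_that("training rejects degenerate cohorts", {
  m <- build_model(model_config(), seed = 1)
  awake <- list(list(
    subject_id = "S1", database = "cohortA",
    psg_ref = annotation_set(rep("W", 10), rec_duration = 300),
    hsat_est = annotation_set(rep("W", 10), rec_duration = 300),
    ihr = waveform(rep(60, 600), 2, "ihr"),
    waveforms = list(ppg = waveform(sin(1:30000 / 15), 100, "ppg"),
                     flow = waveform(sin(1:3000 / 6), 10, "flow"))))
  expect_error(train_cardiac(m, awake, train_config("cardiac", iters = 1)),
               "no sleep")
  # the untrained-cardiac warning precedes the label error
  expect_error(suppressWarnings(
    train_end2end(m, awake, train_config("end2end", iters = 1))),
    "no cortical arousal")
})
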