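# small architecture + short schedules for pipeline bookkeeping tests
tiny_model_config <- function() {
  model_config(
    cardiac = list(in_rate = 100, channels = c(4, 4, 6, 6),
                   pool = c(5, 5, 2, 1),
                   dilations = list(c(1, 2), c(1, 2), c(1, 2), c(1, 2)),
                   kernel = 3, head = c(6, 4, 1)),
    resp = list(in_rate = 10, channels = 4, pool = 5,
                dilations = list(c(1, 2)), kernel = 3),
    arousal = list(channels = c(8, 8, 8), pool = c(1, 1, 1),
                   dilations = list(c(1, 2, 4), c(1, 2, 4), c(1, 2, 4)),
                   kernel = 3, head = c(4, 1)))
}

tiny_cohort <- function(n = 8, dur = 900, seed = 5) {
  gen_cohort(cohort_config(n_subjects = n, rec_duration = dur, seed = seed,
                           event_rate = 20))
}
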