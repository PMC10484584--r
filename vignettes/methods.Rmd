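---
title: "Methods: autonomic arousal detection and AHI surrogates for home sleep apnea tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: autonomic arousal detection and AHI surrogates for home sleep apnea tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The apnea-hypopnea index (AHI) counts apneas and hypopneas per hour of
*sleep*, and the AASM scoring rule confirms a hypopnea only when it is
followed by a ≥3% oxygen desaturation *or an arousal*. Home sleep apnea
tests (HSATs) record neither EEG-defined sleep nor cortical arousals, so
the conventional HSAT surrogate — the respiratory event index (REI), which
divides desaturation-confirmed events by total recording time — is biased
downward: the denominator is too large (wake time counts) and the numerator
too small (arousal-only hypopneas are missed). `hsatscore` implements the
two surrogate signals that repair this: a cardio-respiratory estimate of
sleep (consumed as an estimated hypnogram) and an autonomic-arousal
detector operating on photoplethysmography (PPG) and respiratory flow, plus
the scoring rules and the agreement statistics needed to evaluate the
result against polysomnography (PSG).

## Time conventions and annotations

All times are seconds from recording start; intervals are half-open
`[onset, onset + duration)`, which removes boundary double-counting. Sleep
is staged in fixed 30-s epochs over {W, N1, N2, N3, R}; epoch *i* covers
`[30i, 30(i+1))`. The hypnogram has `ceiling(rec_duration / 30)` epochs. A
partial final epoch counts its full 30 s toward total sleep time (TST) when
it covers at least 15 s, and pro rata otherwise — the guideline literature
is silent here, and pro-rata truncation avoids inflating TST from a sliver
of a final epoch. Annotations round-trip through a canonical JSON schema
(versioned, fixed field order); waveforms through a plain CSV dialect or
16-bit EDF.

## Scoring rules

* **Wake filtering.** Apneas/hypopneas count only if their interval
  overlaps at least one sleep epoch. Arousals count if they start during
  sleep or within the first or last 15 s of a maximal wake run (the
  tolerance captures arousals that cause awakenings).
* **Hypopnea confirmation.** A hypopnea is confirmed by a ≥3%
  desaturation starting within `[onset, end + 45 s]` or (in the
  arousal-augmented mode) an arousal starting within `[onset, end + 5 s]`.
  The two windows are configuration, not doctrine: the auto-scoring systems
  that produce such annotations do not publish their association windows,
  so we default to a 45-s circulatory delay for desaturations and a tight
  5-s window for arousals, and no test or bundled result depends on the
  choice. Desaturations pair one-to-one with hypopneas (greedily by
  proximity), so one desaturation cannot confirm two events. This makes the
  arousal-augmented index provably ≥ the desaturation-only index on the
  same inputs.
* **Indices.** `rei` uses the full recording duration as denominator with
  no sleep filtering (a bare HSAT knows nothing about sleep); `ahi_cress`
  and `ahi_cress_autar` use sleep-filtered events over estimated TST. The
  reference `ahi_psg` applies the same machinery to the PSG annotations
  with cortical arousals. Severity bins are left-closed at 5, 15 and
  30 events/h.

## The detector

Three modules of residual blocks built from stacked dilated 1-D
convolutions (kernel 3, dilations doubling 1-2-4-8), each block closing
with a 1×1 dense combination, a residual connection and temporal max
pooling:

* **cardiac**: PPG at 100 Hz (0.3 Hz zero-phase high-pass) → four blocks
  pooling 5·5·2·1 → 2 Hz → three time-distributed dense layers regressing
  normalized instantaneous heart rate (IHR);
* **respiratory**: flow at 10 Hz (0.03 Hz high-pass) → one block pooling
  5 → 2 Hz;
* **arousal**: the concatenation of the cardiac output and the respiratory
  features → three blocks without pooling (the first with dilations up to
  16) → two dense layers → sigmoid probability at 2 Hz.

By default the *only* cardiac input to the arousal module is the single
2 Hz IHR value (`wiring = "ihr"`), which keeps the detector agnostic to the
cardiac sensor; feeding the cardiac head's penultimate features instead is
available behind `wiring = "features"`. The default configuration has a
total receptive field of 85.3 s (≈ ±43 s of context); `build_model()`
verifies that pooling lands exactly on 2 Hz and warns outside the 80-100 s
receptive-field band. Channel widths (8-12-16-16 cardiac, 8 respiratory,
16-16-16 arousal) and dense widths are desk-scale defaults — publications
in this area do not fix them — chosen to satisfy the rate and
receptive-field constraints while training in minutes on one CPU.

**Training** is two-phase. Phase 1 trains the cardiac module alone against
ground-truth 2 Hz IHR with mean-absolute-error loss and temporal stretch
augmentation: a factor *f* is drawn uniformly in `[0.8, 1.2]` per window,
the input covers `window/f` seconds resampled to `window` seconds, and the
IHR target is divided by *f* (a squeezed recording appears to beat faster).
Phase 2 trains end-to-end with (positively weighted, default 5×) binary
cross-entropy against 2 Hz cortical-arousal indicator sequences while the
cardiac parameters are frozen — verified by hashing them before and after.
The optimizer is Adam (lr 2·10⁻³) on gradients computed by exact
backpropagation through the convolution/pooling stack; convolutions are
evaluated as sums of shifted matrix products so that all heavy computation
is BLAS. Losses (MAE, BCE), optimizer and schedule are standard choices;
none are dictated by the method itself. Fixed seeds give bit-identical
runs on one CPU.

**Events.** Probability runs *strictly above* the calibrated threshold
lasting at least 2 s (4 samples at 2 Hz, each covering 0.5 s) become
autonomic arousal events. We read "exceeds" as strict; the boundary case is
measure-zero in practice but is pinned by tests. No post-hoc merging of
nearby events and no minimum inter-arousal separation is applied — nothing
in the method calls for either. The threshold is chosen per
cross-validation fold by maximizing event-level F1 on the training folds
over a 0.01-step grid, ties broken toward the larger (more conservative)
threshold. Event matching for F1 is greedy one-to-one in onset order with
any-overlap as the match criterion; since the published method leaves its
matching rule unstated, ours is explicit and configurable machinery, used
only for calibration and synthetic evaluation.

**Cross-validation.** Subjects are split into four folds stratified by
database, pseudo-randomly from a fixed seed. Each fold is scored by the
model trained on the other three, with the threshold calibrated on those
three; the run manifest records folds, seeds, thresholds and cardiac
hashes, and tests probe the no-leakage property directly (corrupting a
validation subject's reference labels does not change its predictions).

## The synthetic generator

The generator is first-class code, not a fixture: it defines the study
conditions under which the detector and the scoring rules are exercised.

* Hypnograms are Markov chains on 30-s epochs starting in wake, with a
  transition matrix giving realistic bout structure (sustained N2/N3/R
  runs, brief N1).
* Respiratory events (10-60 s, uniform; the AASM 10-s minimum) occur at a
  Poisson rate per sleep-hour with onsets in sleep epochs; collisions are
  re-placed rather than dropped so the realized count keeps the configured
  rate. Events are apneas (obstructive/central/mixed 6:3:1) or hypopneas
  (half), a hypopnea draws a ≥3% desaturation (depth 3-8%, lag 10-30 s
  modelling circulatory delay) with probability 0.7, any event ends in a
  cortical arousal with probability 0.6, and spontaneous cortical arousals
  add 10/h of sleep.
* Autonomic arousals copy cortical ones with probability 0.85 (small onset
  jitter) plus spurious autonomic-only arousals per respiratory event with
  probability 0.10, emulating the known discordance (e.g. limb-movement
  arousals without cortical correlates). The realistic joint distribution
  of that discordance is unknown; the knob is a knob, not a claim.
* IHR is baseline (per-subject ~N(65, 6²) bpm) plus smoothed HRV noise
  (sd 3 bpm) plus a surge per arousal: linear 2-s rise, 8-s exponential
  decay, peak 25 bpm — a typical post-arousal tachycardia shape; the
  method's source does not model the autonomic response, so this kernel is
  the generator's own design. PPG renders beats (obtained by integrating
  IHR/60) as raised-cosine-squared pulses with 5% amplitude jitter; flow is
  a 12-18 breaths/min sinusoid whose envelope drops to 0.4 during
  hypopneas (the ≥30% excursion-reduction rule) and 0.05 during apneas
  with ≤2 s transitions; SpO2 is generated for completeness but only
  desaturation *annotations* are consumed downstream.
* The estimated annotation set corrupts the hypnogram with a per-epoch
  confusion matrix (emulating cardio-respiratory sleep staging error) and
  carries the autonomic arousals.

What passing tests on this generator do show: the network can recover IHR
from a pulse waveform and detect arousal-linked tachycardia against
realistic event structure; the scoring rules and statistics are exact. What
they do not show: performance on real recordings — real PPG morphology,
arrhythmia, motion artifacts, sensor detachment and true
autonomic/cortical discordance are all absent, so the published real-data
agreement numbers (e.g. an arousal-index ICC of 0.73) are *not*
reproduced here and no synthetic result should be read as a clinical
claim.

## Statistics

All formulas are implemented directly and cross-checked against
independent oracles in the test suite:

* **ICC(A,1)** — two-way random effects, absolute agreement, single
  measurement, with the McGraw-Wong F-based CI. Absolute agreement is the
  right form because a systematic offset between an HSAT surrogate and the
  PSG AHI is a real disagreement.
* **Bland-Altman** — bias ± 1.96 sd with a t-based CI for the bias and the
  large-sample `sd·sqrt(3/n)` standard error for each limit.
* **Wilson score intervals with continuity correction** for all binomial
  proportions; **Simel log-method CIs** for likelihood ratios, with
  degenerate cells (sens or spec at 0/1) reported as half-open intervals
  rather than continuity-corrected — matching how such entries are printed
  in the validation literature; **Cohen's κ** with Cohen's 1960 standard
  error.
* **Benjamini-Yekutieli**: sorted `p(k)` against `k·α/(m·c(m))`,
  `c(m) = Σ 1/i`; the reported threshold is the critical value at the
  largest admissible rank (or rank 1's critical value when nothing is
  rejected), and significance flags are exactly `p ≤ threshold`. Entries
  printed as "<0.001" are represented as 0.0005; the resulting threshold is
  verified insensitive to any representation ≤ 0.001.
* **Paired comparisons** (not part of any bundled result): exact McNemar
  for paired proportions; a seeded subject-level bootstrap for κ.

A note on printed precision: evaluation tables in the validation
literature are not consistently round-half-even (one bundled LR entry
prints 9.90 where the counts give 9.8949), so exact-reproduction tests
assert agreement within one unit of the last printed digit.

## Alignment

Dual recordings sharing a flow channel are aligned by normalized
cross-correlation in moving windows (default 120 s window, 60 s step, both
signals resampled to 10 Hz — breathing-band structure needs no more), with
parabolic interpolation around each correlation peak for sub-sample lags.
A least-absolute-deviations line `lag(t) = shift + drift·t` (IRLS) over
windows with peak correlation ≥ 0.5 gives the clock model; fewer than two
admissible windows raises an alignment-impossible error, mirroring the
practice of excluding unalignable recordings. Timestamps map as
`t → t(1+drift) + shift`. The admissibility threshold and window geometry
are documented defaults; recovery is validated on 200 randomized trials
(shift ±30 s, drift ±5·10⁻⁴), requiring the shift within one sample period
and the drift within 10% relative error, floored at one sample period
accumulated over the recording (a drift whose total effect is below one
sample is unmeasurable in principle).

## Problem sizes and numerical choices

The bundled validation uses: 500 random annotation sets for scoring-oracle
equivalence; 1,000 random series for event-extraction equivalence; a
20-subject × 1-h cohort with 400 Adam steps per phase for the training
check (held-out IHR MAE < 5 bpm; event F1 ≥ 0.6 — the observed run reaches
≈1.1 bpm and ≈0.78); 200 alignment trials on 4,000-s signals; and a
60-subject cohort for the synthetic agreement statistics. These sizes are
the package's chosen desk-scale study conditions: large enough for the
Monte-Carlo tolerances used, small enough to run routinely. Degenerate
inputs (zero variance, empty classes, zero sleep time with countable
events, chance agreement of 1) raise explicit errors rather than NaNs.

## Known limitations

* The detector is validated only on synthetic physiology; no claim
  transfers to real recordings without retraining and clinical validation.
* Arrhythmia, PPG artifact models, and REM-related patterns are not
  simulated.
* The CReSS-style sleep stager itself is out of scope: estimated
  hypnograms enter as annotations (or via the corruption model), never
  computed from waveforms.
* Respiratory event *detection* from flow is likewise out of scope; events
  are consumed as annotations, and only their arousal/desaturation
  confirmation is re-scored.
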