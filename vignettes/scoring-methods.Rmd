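---
title: "How somnoscore scores rodent sleep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How somnoscore scores rodent sleep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

somnoscore turns a day of chronic rodent electrophysiology — one or two
EEG/LFP channels plus a nuchal EMG, nominally 250 Hz — into a hypnogram:
a label of wake (`W`), NREM sleep (`NR`), or REM sleep (`R`) for every 4 s
epoch. The design goal is the one that matters in practice for sleep labs:
an experimenter hand-scores only a small, well-chosen fraction of the
recording (560 epochs, about 2.6% of a day), and the classifier scores the
rest, flagging the epochs it is unsure about so they can be rescored by eye
if desired.

This vignette explains the model, its assumptions, the tunable parameters,
the synthetic data the package validates itself on, and the numerical
choices made where the design was genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The feature set

Sleep states in rodents are separable almost entirely in band power and
muscle tone: NREM shows high-amplitude slow (delta) activity, wake and REM
show low-voltage activity with a theta peak, wake carries broadband gamma
and high, variable EMG tone, and REM is defined by muscle atonia. The
classifier therefore works from 17 features per configuration (13 per brain
channel + 4 EMG-derived):

* Eight band-limited powers per brain channel from a Welch spectrum of each
  4 s epoch: delta 1–4, theta 4–7, upper theta 7–9, alpha 8–12, beta 13–30,
  low gamma 30–50, medium gamma 50–75, high gamma 76–125 Hz. The band table
  deliberately contains an overlap (7–9 vs 8–12) and two gaps (12–13,
  75–76 Hz); it is reproduced as printed in the scoring convention it
  implements rather than tidied, since the network does not care about
  overlap and tidying would silently change the features.
* Five band ratios per channel: beta/delta, beta/low gamma, beta/high
  gamma, theta/delta, theta/medium gamma.
* EMG RMS of the raw samples and total 0.5–125 Hz EMG spectral power.
* Two wake/REM disambiguators: each EMG feature summed with the medium
  gamma power (averaged across brain channels when there are two).

Welch parameters are 2 s Hamming-windowed segments with 50% overlap — three
averaged segments per epoch and 0.5 Hz resolution, enough to resolve the
0.5–4 Hz slow-wave band. The estimator is scaled so band powers integrate
to signal variance (a Parseval check is part of the test suite). Band edges
follow `[low, high)` on bin centers, with the topmost band closed at 125 Hz.

All features are z-scored (sample SD, *n* − 1) before entering the network.
Statistics are fit on the whole recording: normalization is what makes a
model transferable across days and animals, so a test recording is always
z-scored with its *own* statistics (`generalize()`).

Ratio features guard against zero denominators with a floor of
`1e-12 × mean broadband power`; real spectra never reach it, it only
protects degenerate synthetic input (an all-zero channel).

## The classifier

A deliberately small feed-forward network: fully connected layers of 256,
128, and 32 ReLU units and a 3-unit softmax output, trained to minimize
categorical cross-entropy plus an L2 weight penalty (β = 0.01, biases
excluded) with Adam (learning rate 0.001), 100 complete passes in
minibatches of 10, no early stopping and no validation split. These
hyperparameters are the package defaults in `network_spec()` and are fixed
values, not tuned per recording.

The 560-epoch training set is assembled by `select_training_epochs()`:
50 pseudorandom non-overlapping series of 10 consecutive epochs, with
series starts stratified so every 2 h bin of the recording is represented
when possible, resampled (bounded retries) until all three states appear;
plus 60 additional REM epochs sought outside the series, because REM is
naturally rare. Class imbalance is then removed by resampling minority
classes with replacement up to the majority count (`oversample_balance()`)
— the standard choice that never discards data.

Training is repeated five times from different seeds (initialization and
batch order), giving an ensemble of similar but distinct networks. For each
epoch the predicted state is the modal per-member argmax; a 2–2–1 vote is
broken toward the state with the higher mean probability. Certainty is the
mean probability the members assign to that modal state, and an epoch with
certainty below 0.90 is flagged *uncertain*. The flag is the interface for
optional human-in-the-loop rescoring (`merge_manual_rescore()`), which only
accepts labels for flagged epochs — the triage contract.

The network itself is implemented in compiled code (RcppArmadillo) with a
private seeded RNG: Glorot-uniform initialization and per-pass batch
shuffling are reproducible bit-for-bit under a seed and never touch R's
RNG state. A NaN loss aborts with a hint about feature scaling, rather
than training silently into garbage.

## Heuristic post-processing

The network scores epochs independently, so it cannot use sleep/wake
history. Three rules amend the hypnogram afterwards:

1. `fill_rem_gaps()` — runs of non-REM labels lasting at most 12 s
   (3 epochs) with REM on both sides become REM (REM continuity).
2. `forbid_wake_to_rem()` — REM immediately after wake is rescored as wake;
   direct wake→REM transitions are essentially pathological in rodents.
3. `smooth_isolated()` — a single epoch whose two neighbors agree with each
   other but not with it takes their label (one simultaneous pass).

Open design points, decided as follows. The rules are applied in the order
above and the cycle is iterated to a global fixed point: a single pass
leaves rule interactions order-dependent, while the fixed point is
idempotent and reproducible (the suite checks equivalence against a
brute-force oracle on all 3^8 length-8 hypnograms). The wake→REM rule
rescored run-wise, since repeated application of the printed single-epoch
rule cascades through the run anyway — and the gap-filling rule runs first,
so genuine REM fragmented by brief arousals is already protected; the
literal single-epoch variant remains available
(`rescore_whole_run = FALSE`). "Bouts of waking or NREM" inside REM are
read as runs of any W/NR mixture; the conservative pure-run reading is
`mixed_gap_runs = FALSE`. The first and last epochs are never altered —
every rule needs both neighbors to be defined.

## The EMG quality gate

REM is recognized by atonia, so scoring fails when the EMG is
uninformative. Before training, the coefficient of variation of per-epoch
RMS EMG (sample SD / mean, over all epochs of the recording) is compared
with the threshold 1.67; below it, the pipeline warns that REM scoring is
unlikely to succeed and refuses to continue without `force = TRUE`. The CV
is scale-free, so amplifier gain does not matter. The RMS window is the
4 s scoring epoch, consistent with the RMS feature; the gate's source
convention does not state a window, and this is the natural one.

## Evaluation and sleep parameters

`confusion()` and `metrics()` report overall accuracy and one-vs-rest
per-state sensitivity TP/(TP+FN) and specificity TN/(TN+FP), in percent.
Epochs a human flagged as artifact (but still assigned a state) can be kept
(`include_artifact`, the default) or dropped; a state absent from the truth
yields `NA` sensitivity, not zero. Downstream parameters: per-state spectra
normalized to mean 0.5–125 Hz broadband power; the slow-wave-activity
timecourse (0.5–4 Hz NREM power per light-period hour, normalized to the
light-period mean — values average to 1 by construction, hours without
NREM are excluded from the mean); state durations split light/dark by
per-epoch attribution (bouts spanning the boundary split proportionally);
and mean bout durations over the whole day.

## The synthetic generator

`synth_config()` + `generate_dataset()` produce seeded recordings with
ground truth so every stage is testable without data downloads. State
sequences come from a semi-Markov process (lognormal bout durations;
medians W 120 s / NREM 160 s / REM 80 s; transitions W→NR only, NR→W 0.6 /
NR→R 0.4, R→W 0.7 / R→NR 0.3; light/dark bout-length modulation ×1.3 for
sleep in the light phase) chosen to give rodent-like state fractions
(roughly 40/50/10 W/NR/R) with REM entered only from NREM. Signals are
spectrally shaped Gaussian noise: a 1/f² background plus state recipes —
NREM delta gain with a linear decline across the light period (sleep
homeostasis), a shared 7 Hz theta peak for wake *and* REM, and a modest
broadband gamma gain for wake only. EMG is state-level Gaussian noise
(W 1.0 ≫ NREM 0.25 > REM 0.15) with lognormal within-state level jitter
and large lognormal wake bursts; the burst variability is what pushes the
EMG CV above the 1.67 gate, and analytic computation puts the default CV
near 2 while a flat (failed-electrode) EMG sits far below it.

Three choices matter for what the tests mean. First, the state-specific
gains (delta 1.5, theta 1.5, gamma 0.5, each with per-epoch lognormal
jitter, sdlog 0.5) sit near the sampling variability of a 3-segment Welch
estimate, so classification is good but not at ceiling — errors exist and
concentrate where they should. Second, 30% of wake epochs are *quiet
wakefulness*: drowsy immobility with almost no gamma, reduced muscle tone,
and no movement bursts. Quiet wake is spectrally near-identical to REM, so
telling them apart hinges on the EMG exactly as it does for human scorers —
and flattening EMG contrast (the `emg_sweep` experiment interpolates all
state levels to their geometric mean, emulating a failed electrode)
therefore degrades REM sensitivity specifically. Third, state transitions
are crossfaded over 0.5 s so boundary epochs are genuinely ambiguous and
the uncertainty mechanism has something to flag.

What the generator does *not* emulate: spindles, K-complexes, phasic REM
events, artifacts, electrode drift, inter-animal variability beyond
parameter perturbation. Passing tests therefore demonstrate that the
pipeline machinery is correct and well-calibrated on band-power-structured
signals; they do not certify performance numbers on any real recording.

## Problem sizes and determinism

The validation suite runs scaled-down days — 0.5–2 h for pipeline tests and
the acceptance script's main run, 1.5 h for the experiment grids, 24 h only
for label-level simulations that need no signals — sizes chosen so the full
suite completes in minutes on a single CPU while every epoch-level property
is exercised at full feature dimensionality. Every stochastic step
(hypnogram simulation, signal synthesis, training-epoch selection,
oversampling, network initialization and batch order) consumes an explicit
seed, and identical configuration plus seed reproduces byte-identical
hypnogram files end to end.

## Known limitations

Only the three standard rodent states are scored; transitional/artifact
epochs are not modeled (artifact-flagged epochs are still scored, matching
the evaluation convention). The classifier is epoch-independent; history
enters only through the three heuristic rules. Cross-animal transfer
degrades, REM sensitivity first — the generalization experiment reproduces
that pattern qualitatively. The EDF writer quantizes to 16 bits (a property
of the format); the float64 binary format round-trips exactly.
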