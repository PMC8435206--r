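# somnoscore

Automated wake/NREM/REM scoring of chronic rodent EEG/EMG recordings.

Sleep labs record days of electrophysiology — typically two EEG/LFP
channels and one nuchal EMG at 250 Hz — and someone has to label every 4 s
epoch as waking (`W`), NREM sleep (`NR`), or REM sleep (`R`). Doing that by
eye takes hours per recording day. somnoscore automates it while keeping
the experimenter in the loop where it matters: you hand-score a small,
well-chosen training set (560 epochs, ~2.6% of a day), the package trains a
small ensemble of feed-forward neural networks on spectral and EMG features
of those epochs, scores everything else, and flags the epochs it is unsure
about so you can rescore just those by eye if you want extra accuracy.

## The method

Per 4 s epoch and brain channel, a Welch spectrum (2 s Hamming segments,
50% overlap) yields eight band-limited powers

> delta 1–4, theta 4–7, upper theta 7–9, alpha 8–12, beta 13–30,
> low gamma 30–50, medium gamma 50–75, high gamma 76–125 Hz

and five ratios (β/δ, β/γ_low, β/γ_high, θ/δ, θ/γ_mid); the EMG contributes
its RMS and total 0.5–125 Hz power, each also summed with medium-gamma
power as a wake/REM disambiguator. All features are z-scored. The
classifier is a 256–128–32–3 fully connected ReLU network with softmax
output, trained to minimize categorical cross-entropy with an L2 penalty
(β = 0.01) by Adam (lr 0.001, batch 10, 100 passes) on the class-balanced
(minority-oversampled) training set. Training is repeated five times from
different seeds; the predicted state is the ensemble's modal vote, and the
mean probability of that state is the epoch's *certainty* — below 0.90 the
epoch is flagged for optional manual rescoring. Three heuristic rules then
restore sleep-history structure (fill ≤12 s non-REM gaps inside REM, forbid
wake→REM transitions, smooth isolated single epochs), iterated to a fixed
point. Before any of this, an EMG quality gate — the coefficient of
variation of per-epoch RMS EMG must reach 1.67 — refuses recordings whose
EMG cannot support REM scoring.

Downstream, the package computes the standard sleep parameters: per-state
normalized power spectra, the hourly slow-wave-activity (0.5–4 Hz NREM
power) timecourse across the light period, state durations split
light/dark, and bout statistics. A seeded synthetic-recording generator
with ground-truth hypnograms (`synth_config()`, `generate_dataset()`)
makes the whole pipeline testable end to end; see the
`scoring-methods` vignette for the model and its assumptions.

## Worked example

Score a synthetic 2 h recording whose ground truth is known:

```r
library(somnoscore)

cfg <- synth_config(duration_h = 2)        # default study conditions
ds  <- generate_dataset(cfg, seed = 2024)  # recording + truth + 560-epoch-style training set

sc <- score_recording(ds$recording, ds$training, seed = 2024)

held <- setdiff(ds$truth$epoch, ds$training$epoch)
rep  <- metrics(confusion(sc$hypnogram$state[held], ds$truth$state[held]))
glance(rep)
#>   accuracy total   sens_W   spec_W  sens_NR spec_NR   sens_R   spec_R
#> 1 95.56452  1240 95.46926 96.99248 97.25343     100 85.38462 97.56757
```

Read: of the 1,240 epochs the experimenter did *not* score, 95.6% received
the correct label; NREM is nearly perfect, and REM — the hard state, since
quiet wakefulness mimics its EEG — reaches 85.4% sensitivity. The EMG gate
for this recording reports CV 1.93 (≥ 1.67, so REM scoring is viable).
Rescoring only the low-certainty epochs (here with the ground truth
standing in for the human) raises held-out accuracy further:

```r
hyp    <- sc$hypnogram
manual <- tibble::tibble(epoch = hyp$epoch[hyp$uncertain],
                         state = ds$truth$state[hyp$uncertain])
merged <- merge_manual_rescore(hyp, manual)
mean(merged$state[held] == ds$truth$state[held]) * 100
#> [1] 97.09677
```

`autoplot(sc$hypnogram)`, `plot_certainty(sc$prediction)`,
`autoplot(state_spectra(...))` and `autoplot(swa_timecourse(...))` draw the
standard figures. For file-based workflows use `run_score()` (writes the
hypnogram TSV, uncertain-epoch list, model bundle, and a run log) or the
thin CLI at `inst/scripts/sleepscore` with subcommands `simulate`,
`check-emg`, `select-train`, `score`, `rescore`, `evaluate`,
`sleep-params`, and `experiment`.

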