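---
title: "Forecasting seizures from raw EEG: models, data machinery and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting seizures from raw EEG: models, data machinery and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(seizecast)
```

This vignette is the package's account of its science: what is being
modeled, which knobs matter, what the synthetic data does and does not
emulate, and where the design was genuinely open and a choice had to be
made.

## The forecasting problem

Chronic implanted EEG systems record continuously for months to years.
The forecasting task is: given the most recent minute of raw
multichannel signal and the calendar clock, estimate whether a seizure
is imminent. Two properties of this setting shape everything in the
package:

* **labels are defined by time-to-the-next-lead-seizure** — a lead
  seizure has no other seizure in the preceding 4 h, so post-ictal
  signal never contaminates the pre-ictal class; and
* **seizures ride on strong circadian and multidien cycles**, so the
  wall clock itself is informative and is fed to the classifier as
  explicit features rather than left for the network to infer.

The central design commitment is to avoid feature engineering: the
classifier consumes the raw waveform. The payoff is flexibility —
changing the pre-ictal definition (the seizure prediction horizon)
requires retraining only a small fusion classifier on cached network
outputs, not re-deriving features.

## The two-stage model

**Stage 1: the stacked LSTM.** A fixed-duration raw segment (10 s at
the 400-Hz reference scale) is read by four LSTM layers; a temporal
max-pool (factor 4) sits between consecutive layers, so the sequence
shortens 4000 → 1000 → 250 → 62 while unit counts shrink
(64/32/16/8 at reference scale). The first three layers return full
sequences; the fourth returns its final hidden state, which a dense
sigmoid layer maps to one output per label. Targets are one-hot and
the loss is mean-squared error, so each label has its own output
trained toward zero or one; optimization is Adam at learning rate
1e-4. Recurrent dropout (0.25) regularizes the recurrent
transformation.

**Stage 2: the fusion classifier.** Per minute, the five segment
outputs (5 × n_labels values) are concatenated with nine time values —
for each of the hour-of-day (24 h), day-of-month (fixed 31 d),
month-of-year (12 mo) and day-of-week (7 d) cycles, the calendar
position and the time since the cycle start, both scaled to [0, 5] at
1-min resolution; plus `ln(1 + minutes since the last seizure)` — and
passed through dense(10 × n_labels, sigmoid) → dropout(0.25) →
dense(n_labels, sigmoid), trained the same way.

For two-label paradigms the forecast score is the fixed linear
combination `pre − inter`; ROC ordering is invariant to any monotone
linear combination with positive pre-ictal weight, so these weights are
not tunable parameters. Multi-label paradigms are evaluated by
confusion matrices against a *time-matched* random baseline: a random
predictor selecting each label with the model's own selection
proportion has row-normalized sensitivity equal to that proportion, so
any excess is attributable to the model.

### The cell activation

The classical LSTM cell uses tanh for the candidate and cell-state
activations and the logistic function for the gates, and that is the
package default (`activation = "tanh"`). An all-logistic variant
(`activation = "sigmoid"`) is also provided. The all-logistic cell has
a structural weakness we observed directly at desk scale: its candidate
values are strictly positive, so the cell state accumulates a positive
drift and saturates the output nonlinearity, and training reliably
stalls in the constant-output minimum of the MSE loss (loss
`(L-1)/L²` for L balanced labels). The tanh cell trains robustly under
identical conditions, which is why it is the default.

### Training-loop choices

* **Initialization**: Glorot-uniform weights, zero biases except the
  forget gate (bias 1, the standard remedy against early forgetting).
* **Early stopping**: a held-out slice (10%) of the training set; the
  best-validation parameters are kept, with configurable patience. No
  epoch count is canonical; the defaults (30 at reference scale, 20 in
  the desk preset) are engineering choices.
* **Desk preset**: 16/8/8/4 units, learning rate 3e-3. The reference
  learning rate 1e-4 is appropriate for the large model and data
  volume; the tiny desk model on minutes of synthetic signal needs the
  larger step to converge within tens of epochs. For four-label desk
  experiments the final layer is widened to 8 units: a 4-unit final
  state under 0.25 recurrent dropout loses a quarter of its capacity
  at every step and cannot carry four labels.
* **Determinism**: every stochastic element (initialization, epoch
  shuffling, dropout masks, random up-sampling starts) draws from R's
  RNG, so a run is bit-reproducible from its seed on the CPU path.

## Data machinery

**Normalization** is deliberately minimal: per electrode, subtract the
minute mean and divide by the average of the daily signal standard
deviations over a trailing 30-day window, updated once per day. The
30-day divisor carries amplitude information across brain states;
dividing by the minute's own SD would erase it. Missing samples are
replaced by the electrode's minute mean *before* centering, making them
exactly zero afterwards — replacement is neutral by construction. A
minute is excluded when any electrode misses more than one second of
samples (strictly more than 400 at 400 Hz); the threshold is applied
per electrode, reading the two stated clauses ("more than 400 NaNs,
or more than 1 s of data missing") as synonyms. No filtering, artifact
rejection or resampling is performed anywhere.

*Cold start*: a fresh recording has no 30-day history. The divisor
falls back to an expanding window of available daily SDs, and before
any full day exists, to the minute's own SD. Reference deployments
excluded the first 100 days and never faced this; the synthetic desk
runs do. A degenerate divisor (zero, e.g. a constant-signal history)
flags the minute unusable rather than dividing by zero.

**Labeling** uses half-open bins `[lower, upper)` in minutes before the
next lead seizure; "1–16 min" means delta in [1, 16). Inclusivity is
not stated canonically anywhere; half-open bins make the bins partition
the axis exactly. The lead-gap rule is read as an open interval: a
seizure exactly 4 h after the previous one is still lead. Minutes after
the final cataloged seizure have unknowable delta and are excluded by
default (`include_tail` reverses this). The 1-min seizure prediction
horizon is implicit in all bins starting at 1.

**Balancing.** Training sets are balanced by tiered up-sampling of
minority labels: tier 1 takes the even non-overlapping starts (0, 10,
20, ... s), tiers 2 and 3 shift the grid by half and a quarter of the
segment duration, and tier 4 draws random starts on a 2.5-ms grid.
Within a tier, draws rotate round-robin across the label's minutes so
no single minute dominates. The majority label contributes only the
first segment of each of its minutes. Test sets are never balanced:
every eligible minute contributes exactly the five non-overlapping
test-convention segments (a sixth would need overlap on hardware whose
realized rate sits just below nominal, so five is kept by convention
even though the synthetic store is exactly on-rate). The classifier's
minute-level training set is balanced differently — by duplicating
minority rows with independent multiplicative jitter in [0.95, 1.05].

**The split** allocates the first 80% of lead seizures (floor) to
training and places the boundary at the midpoint between the last
training lead and the first test lead, so time-correlated minutes
cannot straddle the sets.

## The synthetic recording generator

The generator produces the *regime* of long-term implanted recordings,
not biophysical EEG:

* per-channel background = AR(1) (pole 0.95) plus white noise — enough
  autocorrelation structure for the autocorrelation-ramp signature to
  be meaningful;
* slow amplitude drift as a log-normal random walk (per-day step SD
  `0.1/sqrt(drift_timescale_days)`, default timescale 30 d) — exercises
  the rolling normalization;
* seizure onsets from a minute-resolution Poisson process modulated
  multiplicatively by configured cycles (`1 + a·cos(2πt/P)` per cycle,
  peaking at the cycle origin and preserving the base rate);
* telemetry dropouts as missing-sample blocks (mask, not sentinel
  values), at an expected rate per day;
* a pre-ictal signature active in a configurable window of
  minutes-before-onset: an additive 25-ms half-sine **marker** at 5×
  the background SD (detectable, far from saturating), a linear
  **variance ramp** (amplitude × `preictal_scale` at onset), or an
  **autocorrelation ramp** (AR pole toward 0.995 at onset).

Defaults where no canonical value exists were fixed once: 6
seizures/day at desk scale (so a 2–3-day simulation contains enough
lead seizures to split), marker insertion at one pulse per second of
pre-ictal signal (a detectability validation should put the signature
in every segment), dropout blocks of 10–30 s a few times per day.

What passing tests on this generator shows: the pipeline's plumbing is
correct end-to-end and the network can extract a genuine waveform
signature it was never told about, at the stated significance rule.
What it does not show: performance on clinical EEG, whose pre-ictal
signatures are weaker, non-stationary and patient-specific; nothing
here estimates clinical AUCs.

## The packaged experiments

`marker_recovery_experiment()` — 2 synthetic days, 4 channels at
100 Hz, 2-s segments, marker active 1–15 min before onset; the LSTM is
trained on the balanced segment set and its held-out segment-level AUC
and Hanley–McNeil interval are computed on the unbalanced test
minutes. The pass criterion is the significance rule (lower CI
bound > 0.5); at these conditions the marker is recovered essentially
perfectly.

`signature_placement_experiment()` — 3 days with the marker confined
to 40–80 min before onset and *no* cycles; a four-label LSTM
(bins 1–40/40–80/80–160/>160 min, matched to the short synthetic
inter-seizure gaps) is trained once, its per-minute outputs cached, and
only the fusion classifier is retrained: once on the 40–80-min labels
(which should recover the signature) and once on the 1–4-min labels (a
window holding no signature — the control must stay at chance). Two
conditions keep the control honest: cycles are off, and the lead gap is
set to 1 min so every seizure is lead — with a homogeneous Poisson
schedule the time to the next seizure is then independent of the time
since the last (memorylessness), so the ninth time feature cannot leak
label information structurally. With a long lead gap it does leak: a
minute shortly after a seizure cannot be 1–4 min before a *lead*
seizure, and the control would be "significant" for reasons that have
nothing to do with EEG.

One residual effect cannot be designed away: the marked 40–80-min
minutes are themselves members of paradigm-2's inter-ictal class
(everything beyond 4 min), and a classifier that learns
"signature → not 1–4 min" ranks that subset confidently inter-ictal.
This lifts the control's expected AUC slightly above 0.5 (by roughly
half the marked fraction of the inter class), so over repeated seeds
its confidence bound occasionally clears 0.5 even though the 1–4-min
window holds no signature. The packaged experiment evaluates at its
fixed seed; the comparison that carries the scientific weight is the
gap between the retargeted 40–80-min AUC (essentially 1) and the
control (near chance).

Problem sizes (2–3 simulated days, ~6 seizures/day, tiny LSTM) were
chosen so a full experiment runs in one to two minutes on a single CPU
while leaving hundreds of test minutes in each class.

## Evaluation semantics

* ROC: threshold sweep over unique scores, predicting positive at
  `score ≥ threshold`; ties advance the curve diagonally, so the
  trapezoidal AUC equals the Mann–Whitney statistic with half-credit
  for tied pairs. Degenerate inputs (one class absent) are errors, not
  silent 0.5s.
* Hanley–McNeil: `SE² = [A(1−A) + (n₊−1)(Q₁−A²) + (n₋−1)(Q₂−A²)]
  /(n₊n₋)`, `Q₁ = A/(2−A)`, `Q₂ = 2A²/(1+A)`, half-width `1.96·SE` at
  the default 95% level. Two AUCs differ significantly when their
  intervals do not overlap; an AUC beats chance when its lower bound
  exceeds 0.5. Note the interval collapses at A = 1.
* Sensitivity is **sample-level** (every pre-ictal minute must be
  classified pre-ictal), deliberately stricter than the per-seizure
  event scoring of comparison models; time-in-high is the fraction of
  all predictions in warning, on the same clock, so the two quantities
  are directly comparable along the curve. `match_point()` minimizes
  the absolute distance to a target, breaking ties toward the lower
  time-in-high (the cheaper operating point).
* Multi-label prediction is argmax with lowest-index tie-break.

## Numerical and storage details

* Integer minute indices (half-open intervals everywhere) with a
  calendar epoch; the default epoch is a Monday, January 1st, so all
  cycle origins coincide at minute 0. The day-of-month cycle is fixed
  at 31 days regardless of the actual month; the month-of-year pair
  uses real calendar month lengths.
* The log time-since-seizure is capped at 60 days (`ln(1+86400)`),
  which also serves as the value before the first cataloged seizure;
  no canonical normalization exists for this term, so the cap simply
  keeps it bounded and finite.
* Minute payloads are stored one little-endian binary file per minute
  (doubles plus missing-sample indices) with a CSV manifest; the
  round-trip is bit-lossless. EDF+ export writes 1-s data records,
  16-bit samples against a per-channel symmetric physical range, zeros
  for missing samples and `dropout` annotations in the EDF Annotations
  channel.
* The LSTM forward/backward pass is compiled (RcppArmadillo); analytic
  gradients are verified against central finite differences in the test
  suite, and the recurrence against an independent per-step R
  implementation to 1e-5.

## Known limitations

* The generator's seizures have no ictal morphology — the minute of
  the onset itself is ordinary background (and is excluded from
  datasets anyway).
* Pooling floors the time axis, discarding up to `pool−1` trailing
  steps per stage.
* Training at the full reference scale (16 ch × 400 Hz × months) is
  out of scope for a single CPU; the package's defaults expose the
  reference hyperparameters, but the shipped experiments run the desk
  preset.
* The per-patient clinical results of the source study are not
  reproducible without the clinical recordings and are not attempted:
  acceptance is structural and property-based by design.
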