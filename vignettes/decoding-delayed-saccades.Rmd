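---
title: "Decoding free versus instructed saccades from intracranial band-envelope power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding free versus instructed saccades from intracranial band-envelope power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freesacc)
```

## The problem

In a delayed oculomotor decision task, a participant sees a central cue
(Cue 1, 250 ms) that either instructs a saccade direction (*Instructed*),
invites a free choice between left and right (*Free*), or announces that the
direction will only be revealed at the go signal (*Control*). After a variable
delay of 3,750, 5,750 or 7,750 ms, a go cue (Cue 2) triggers the saccade.
Depth-electrode (SEEG) recordings during such tasks show that the envelope of
broadband high-gamma activity (HG, 60–140 Hz) — a proxy for local population
firing — carries enough information to classify the trial type on single
trials, and that the *temporal profile* of that information (transient for
instructed planning, delayed and sustained for free choice) is itself the
scientific signal of interest.

`freesacc` implements this analysis end to end as a reusable, tested
pipeline: a seeded synthetic-data generator that emulates the task and its HG
effects, EOG-based behavioral processing, band-envelope feature extraction,
time-resolved and cross-temporal linear-discriminant decoding with
permutation maximum-statistics inference, temporal-dynamics metrics, and
conjunction mapping of choice-specific sites. Because no public recording of
this task exists, the generator is a first-class module: it provides the
ground truth against which every stage of the pipeline is validated.

## The synthetic-data generator

`sim_config()` encodes the study conditions: three interleaved conditions at
33.3% each, the delay set above, a 250 ms cue, a 1,500 ms intertrial gap,
1,024 Hz sampling, and per-condition saccade-latency distributions
(Control 466 ± 66, Free 334 ± 36, Instructed 321 ± 33 ms; mean ± SD).
A configurable fraction of trials (default 25%) receives a spontaneous
delay-period eye movement so that behavioral screening retains roughly 75% of
trials, as in the recordings the task emulates.

Neural signals are synthesized as

* a broadband 1/f background (`noise_spec()`, exponent 1, scale 0.3) plus a
  weak alpha-band sinusoid. The underlying studies report no noise model, so
  these are explicit assumptions, chosen to give realistic single-trial
  envelope variability, and exposed in the configuration;
* per-site band-limited carriers (unit RMS, HG by default) whose envelope is
  modulated **multiplicatively**, `carrier * (1 + a * s(t))`. Multiplicative
  modulation of filtered noise keeps HG broadband — an additive sinusoid
  would concentrate power at one frequency and be trivially decodable for the
  wrong reason.

Effect shapes (`effect_spec()`): *transient* is a Gaussian bump with
`sd = duration/4`; *sustained* a raised-cosine-edged plateau of fixed
duration; *persistent* a plateau lasting until the go cue regardless of the
delay; *execution* a ramp-plateau locked per trial to the saccade latency
(plus Gaussian jitter, default SD 30 ms), which gives the HG-onset ×
reaction-time correlation a known ground truth. The default effect map
calibrates to the printed dynamics of the task: Instructed transient +39%
peaking at 475 ms, Free sustained +24% with onset 465 ms, on four of eight
sites; one site carries a persistent Free effect (so conjunction analyses see
an "early + late" site); three sites are null during the delay. Because
latencies shape the execution effect, they are drawn before signal synthesis;
`synthesize_eog()` still writes them back into the trial table, which is the
generator's public contract.

What the generator does **not** emulate: epileptic waveforms, electrode
geometry and volume conduction, non-stationary noise, cross-site correlation
of the background, or behavioral drift across the session. Passing tests on
synthetic data therefore demonstrate the correctness and calibration of the
*machinery*, not the reproduction of any patient dataset. Generator channels
stand for bipolar derivations directly; `bipolar_rereference()` is available
(and tested) for recordings that arrive as monopolar contacts on shafts.

## Feature extraction

Each channel is band-passed with a zero-phase FIR filter and enveloped with
the magnitude of the analytic signal (`band_envelope()`), then averaged over
sliding windows (`windowed_power()`, `epoch_features()`). Defaults follow the
analysis this package reimplements: bands θ 4–8, α 8–15, β 16–30, low-γ
30–60, HG 60–140 Hz; 400 ms windows stepped by 50 ms over [−500, 2500) ms
around Cue 1 and [−500, 1500) ms around Cue 2; a 60 ms window grid for
single-trial displays.

Numerical choices worth knowing:

* **Window stepping.** "400 ms windows with an overlap of 50 ms" is read as a
  50 ms *hop* (349 ms of overlap), the reading consistent with the smooth
  time-resolved curves the analysis produces; a literal 50 ms overlap is a
  single argument change (`step_ms = 350`).
* **Filter length.** A literal "order 3" FIR band-pass cannot exist; the
  filter length is three cycles of the band's lower edge (a common toolbox
  convention), forced odd so the group delay is integral. Zero phase is
  obtained in one pass by FFT convolution with the symmetric filter and exact
  group-delay compensation — equivalent, for a linear-phase FIR, to the usual
  forward–backward scheme, at half the cost. One filter length at each signal
  edge is flagged unreliable (`edge_samples` attribute).
* **"Power".** The analytic magnitude (envelope) is used as the power
  feature, matching the relative-percent scale of the reported dynamics;
  squared magnitude changes nothing structurally.
* **Windows** are half-open `[t, t + L)`; the value is reported at the centre
  `t + L/2`. Baseline normalization `(x − b)/b` uses the mean over windows
  inside [−500, −100) ms before Cue 1; degenerate baselines (`b ≤ 0`) flag
  the trial rather than divide. Normalized power is used for visualization
  and dynamics only; **classification always consumes raw power**.

## Decoding and inference

The classifier is a two-class linear discriminant with pooled within-class
covariance, Ledoit–Wolf analytic shrinkage and equal priors, written for this
package (`cross_validated_da()`). Shrinkage matters because multisite feature
spaces can approach the trial count; with a single feature it reduces exactly
to the midpoint rule, which is what the vectorized per-cell path exploits to
make permutation testing cheap. Equal priors make decoding accuracy invariant
under swapping the two class labels. Stratified 10-fold cross-validation
tests every trial exactly once; folds are reduced (with a message) when the
smaller class is smaller than the fold count, and fold assignment is a
deterministic function of the seed and of the class *partition* (not the
label names).

Inference (`permutation_maxstat()`): labels are shuffled once per permutation
and the **same** shuffled labels are reused across every site, band and
window — a requirement for a valid maximum distribution; the full DA array is
recomputed per permutation; the null is the distribution of its global
maximum; the threshold is the `ceiling((1−α)(n+1))`-th order statistic (with
n = 100, α = 0.01: the largest null maximum); cells are significant strictly
above it. This controls the family-wise error across electrodes, bands and
time. The fold partition is held fixed under permutation.

Cross-temporal generalization (`temporal_generalization()`) trains fold-wise
classifiers at each window and tests them on the *same fold's held-out
trials* at every other window, so off-diagonal cells involve no leakage and
the diagonal equals per-window cross-validated decoding under the same folds
(this is asserted in the tests). Its significance threshold is the exact
binomial tail on the total held-out count (`binomial_da_threshold()`); the
total count is used because the per-fold count is not what the accuracy is
averaged over. Exhaustive band selection (`exhaustive_band_selection()`)
scores all 31 nonempty subsets of the five bands on each of three disjoint
stratified validation thirds; ties prefer the smaller subset, then band
order.

## Dynamics and conjunction

`peak_metrics()` reports the maximum relative HG change and its latency (ties
to the earliest window). `decoding_onset_duration()` defines onset as the
first significant window and duration as the step times the **total** count
of significant windows, so non-contiguous significance accumulates — the
counting rule, not the run-length rule. Per-trial HG onsets
(`detect_hg_onset_trial()`) use the "2 SD above baseline for ≥ 2 consecutive
bins" rule on **disjoint** bins (step = window length). The disjoint-bin
reading is deliberate: on a heavily overlapping grid a 400 ms window smears
any onset estimate by several steps, whereas with disjoint bins the detection
error is bounded by one bin width at any signal-to-noise ratio above
threshold. The baseline statistics feeding the rule come from the pre-cue
window, pooled across trials: a single trial contributes only seven 60 ms
baseline bins, far too few for a stable SD estimate, and an underestimated SD
turns the 2-SD rule into a false-alarm generator. In the pipeline the search
is further restricted to post-go bins, since execution-locked HG cannot
precede the go cue. The source analysis specifies neither choice.

The onset × reaction-time correlation is Pearson on raw latencies (the
"Pearson's rank correlation" phrase in the source literature is internally
contradictory; Spearman is available by flag). One generator property worth
stating: within a single condition, the calibrated latency spread (SD ≈ 36 ms
for Free) against the 30 ms onset jitter caps the attainable correlation near
0.77 even with perfect detection; pooling the three conditions (latency SD ≈
80 ms) is what makes r > 0.8 reachable, and is how the synthetic corpus
exercises this machinery.

Conjunctions (`contrast_mask()`, `conjunction_sites()`) intersect sites
significant in two contrasts with required directions, where "significant"
means anywhere within the window of interest (the stricter same-window
reading is not used); *early* is [0, 2000) ms after Cue 1 and *late*
[−2000, 0) ms before Cue 2, both configurable.

## Problem sizes and reproducibility

The default pipeline (`run_pipeline()`, also driven by a YAML config) runs
four simulated participants with eight sites and 90 trials each at 1,024 Hz —
sizes chosen so a complete run with 100 permutations finishes in minutes on a
laptop while leaving every statistical mechanism (fold reduction, max-stat
correction, conjunction counting) non-trivially exercised. Unit tests use
512 Hz and smaller trial counts for speed; task structure and effect
calibration are never scaled. Everything is deterministic under the master
seed: sub-seeds for schedule, EOG, recording, folds and permutations are
derived from it, and the pipeline's TSV/JSON outputs are byte-identical
across reruns.

## Known limitations

* The noise model is an assumption; absolute decoding accuracies on synthetic
  data depend on it and are not comparable to patient recordings.
* Bootstrap aggregation for unequal-count reaction-time tests reports the
  median p across draws (mean available); how such draws are best combined
  into one p-value is genuinely underdetermined.
* The per-participant peak of a sustained (plateau-shaped) response has an
  intrinsically variable latency — the plateau is flat, so the argmax moves
  — which inflates across-participant variance for that one metric.
* Persistence to EDF/HDF5 is out of scope here; recordings round-trip
  through a documented plain-text container instead
  (`write_recording()`/`read_recording()`).
* Electrode localization, atlas assignment and 3-D rendering are out of
  scope.
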