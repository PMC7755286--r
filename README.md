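# freesacc

Single-trial decoding of free versus instructed saccades from intracranial
EEG band-envelope power.

## What this package is for

In delayed oculomotor decision tasks, a central cue either instructs a
saccade direction (**Instructed**), invites a free left/right choice
(**Free**), or defers the direction to the go signal (**Control**); the
saccade is executed only after a variable delay of 3.75–7.75 s. Depth
(SEEG) recordings during such tasks show that the envelope of broadband
high-gamma activity (HG, 60–140 Hz) discriminates these trial types on
single trials, and that the *temporal profile* of the discriminative signal
— transient for instructed planning, delayed and sustained for free choice —
is the quantity of scientific interest.

`freesacc` is a tested, reusable R implementation of that analysis chain for
researchers working with intracranial (or simulated) recordings:

* **Simulation** (`sim_config()`, `simulate_participant()`): a seeded
  generator of multichannel 1/f-background LFPs with condition- and
  site-specific multiplicative HG-envelope effects (transient / sustained /
  persistent / execution-locked), EOG traces with condition-specific saccade
  latencies, and a full ground-truth record for parameter-recovery testing.
* **Behavior** (`detect_saccade_onset()`, `apply_trial_exclusions()`,
  `compare_reaction_times()`, `trial_history_test()`): EOG slope-based
  saccade detection, latency-ceiling and delay-artifact exclusions,
  bootstrap-equalized reaction-time t tests, and the n−1 trial-history
  conditional-probability permutation test.
* **Spectral features** (`bipolar_rereference()`, `band_envelope()`,
  `epoch_features()`, `baseline_normalize()`): zero-phase FIR band-pass,
  Hilbert envelope, sliding-window mean power on cue-aligned grids
  (400/50 ms analysis grid, 60 ms single-trial grid), relative baseline
  normalization.
* **Decoding** (`cross_validated_da()`, `permutation_maxstat()`,
  `multisite_decoding()`, `temporal_generalization()`,
  `binomial_da_threshold()`, `exhaustive_band_selection()`): two-class
  shrinkage-regularized LDA under stratified 10-fold cross-validation, with
  decoding accuracy

  DA = (1/n) Σ_folds #correct held-out predictions,

  family-wise inference by permutation **maximum statistics** (threshold =
  the ⌈(1−α)(n_perm+1)⌉-th order statistic of the per-permutation global
  maximum DA over all sites × bands × windows), exact binomial chance
  thresholds for cross-temporal generalization matrices, and exhaustive
  selection over all 31 frequency-band subsets.
* **Dynamics** (`peak_metrics()`, `decoding_onset_duration()`,
  `detect_hg_onset_trial()`, `correlate_hg_saccade_onsets()`,
  `group_compare()`): HG peak amplitude/latency, decoding onset and total
  significant duration, per-trial HG onsets by the 2 SD / 2 consecutive-bin
  rule, and HG-onset × reaction-time Pearson correlation.
* **Reporting** (`contrast_mask()`, `conjunction_sites()`,
  `early_late_partition()`, `run_pipeline()`): signed contrast masks,
  conjunction analyses (e.g. Free > Control ∩ Free > Instructed) in early
  [0, 2000) ms post-cue and late [−2000, 0) ms pre-go windows, and a
  deterministic end-to-end pipeline with TSV/JSON outputs.

## Worked example

Simulate one participant under the calibrated defaults, extract high-gamma
features and decode Free versus Instructed trials with max-statistics
correction:

```r
library(freesacc)

cfg <- sim_config(n_participants = 1, n_channels = 8, n_trials = 60,
                  noise = noise_spec(broadband_scale = 0.05), seed = 71)
sim <- simulate_participant(cfg, seed = 71)

tens  <- epoch_features(sim$recording, sim$trials, default_bands(),
                        alignment = "cue1", span_ms = c(-500, 2500))
conds <- sim$trials$condition[sim$trials$included]
keep  <- which(conds %in% c("Free", "Instructed"))
res   <- permutation_maxstat(tensor_subset(tens, trials = keep),
                             factor(conds[keep]), n_perm = 100,
                             alpha = 0.01, seed = 71)
res
#> <decoding_result> Free vs Instructed: 8 sites x 5 bands x 53 windows
#>   max-stat threshold 0.821 (alpha 0.01), 72 significant cells
which(apply(res$sig_mask[, "highgamma", ], 1, any))
#> site1 site2 site3 site4 site5
#>     1     2     3     4     5
```

The five sites that carry injected effects (sites 1–5: Instructed transient
+39% peaking at 475 ms, Free sustained +24%, one persistent Free site) are
exactly the ones whose HG decoding accuracy exceeds the permutation
max-statistics threshold; the three null sites stay below it. The threshold
is the largest of the 100 label-permutation global maxima, so every reported
cell is family-wise controlled at α = 0.01 across all 8 × 5 × 53 cells.

The full pipeline — EOG detection, exclusions, all three pairwise decodings,
temporal generalization, dynamics and conjunctions, written to a report
directory — is one call:

```r
run_pipeline(sim_config(), seed = 1, out_dir = "freesacc-run")
```

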