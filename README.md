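# esporterp

Expertise biomarkers from oddball EEG and cognitive tests.

`esporterp` is an R implementation of a complete analysis pipeline for
two-group (professional vs. novice video-game player) expertise studies
that combine oddball-paradigm EEG with cognitive testing. It is aimed at
cognitive-neurophysiology researchers who want a tested, reproducible
version of this analysis chain, runnable end-to-end on calibrated
synthetic data.

## What it computes

For epoched multi-channel EEG (32-channel 10-20 montage, 250 Hz) across
four oddball paradigms — a non-specific blue/red-ball paradigm (B/RB)
and three game-screenshot paradigms with an enemy of decreasing size
(BT, MT, ST) — the pipeline produces:

- **ERP component tables**: per subject, the P200/N200/P300 amplitude
  (mean within ±10 ms of the windowed extremum, µV) and the 50%
  **fractional-area latency** — the time `t` at which the cumulative
  rectified area under the peak reaches half its total,
  `∫ r(τ)dτ (window start → t) = ½ ∫ r(τ)dτ (whole peak)` — measured on
  the posterior ROI (P3, Pz, P4, PO3, PO4);
- **Hilbert–Huang spectrograms** from variational mode decomposition
  (VMD): the signal is split into K band-limited modes by the ADMM
  scheme `u_k ← (f − Σ_{i≠k} u_i + λ/2) / (1 + 2α(ω − ω_k)²)` with
  power-weighted center-frequency updates, and each mode's squared
  instantaneous amplitude is binned at its instantaneous frequency
  (101 bins, 0–30 Hz);
- **CP tensor decompositions** of space × time × trial and
  space × frequency × time × trial tensors by alternating least squares
  with an orthonormal spatial factor (polar projection each sweep), plus
  per-subject component power (signed sum of trial-factor coefficients)
  compared between groups by the exact Mann–Whitney U test;
- **Permutation statistics**: two-sided label-permutation tests of the
  Welch t statistic, Hedges' g with the exact small-sample correction
  `J(df) = Γ(df/2)/(√(df/2) Γ((df−1)/2))`, and **threshold-free cluster
  enhancement** `TFCE(p) = Σ_h e(h)^0.5 · h² · dh` with family-wise
  max-statistic permutation p-values over 1-D, 2-D and channel-graph
  domains;
- **Cognitive-test group metrics** (reaction times filtered by validity
  thresholds then a 1.5-IQR fence, correct rates, visual-search scores,
  signed target-count errors) and intragroup **Spearman correlation
  maps** between cognitive features, hours in game, and ERP features.

A calibrated synthetic-data generator (`simulate_epochs()`,
`simulate_cognitive_log()`) emulates the two-group study structure from
the shipped reference tables, so the whole chain is testable with no
data download.

## Worked example

Recompute a published group comparison from summary statistics alone
(visual-search final score, 16.90 ± 6.05 vs 19.10 ± 6.37, n = 10 per
group):

```r
library(esporterp)
ref <- cognitive_reference_stats()
r <- ref[ref$test == "VS" & ref$metric == "final_score", ]
compare_group_summary(r$pro_mean, r$pro_sd, 10, r$novice_mean, r$novice_sd, 10)
#>           t       df          g
#> 1 -0.791903 17.95239 -0.3391503
```

The Welch t of −0.79 (t(18) ≈ −0.8) and |g| ≈ 0.34 say the two groups'
visual-search scores are statistically indistinguishable at this sample
size — visual-search skill did not separate professionals from novices.

Simulate a small MT-paradigm data set and compare ERP components between
groups:

```r
e <- simulate_epochs(sim_config(n_subjects_per_group = 5, seed = 42),
                     "MT", targets_only = TRUE)
e
#> <epoch_set> 32 channels x 351 samples x 400 trials @ 250 Hz; 0 rejected
waves <- subject_erps(e)
render_component_table(measure_components_table(waves, "MT"),
                       n_perm = 5000, seed = 1)
#>   component lat_pro lat_novice lat_delta       lat_p amp_pro amp_novice amp_delta       amp_p
#> 1      P200     191        204       -13 0.134920635   13.45       8.68      4.77 0.063492063
#> 2      N200     265        283       -19 0.238095238    9.45       3.60      5.84 0.007936508
#> 3      P300     345        388       -43 0.007936508   17.72      13.17      4.55 0.071428571
```

Even with only 5 subjects per group, the professionals' P300 is 43 ms
earlier (permutation p = 0.008): the generator plants the calibrated
group profiles (PRO P300 at 347 ms vs NOVICE at 389 ms for MT) and the
measurement chain recovers them. At the full 10-per-group study size the
amplitude differences reach significance as well.

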