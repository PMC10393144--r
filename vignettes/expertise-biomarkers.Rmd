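---
title: "EEG and cognitive-test biomarkers of gaming expertise: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG and cognitive-test biomarkers of gaming expertise: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esporterp)
```

# The scientific problem

Professional first-person-shooter players are hypothesized to differ from
novices both behaviorally (faster simple and choice reaction times) and
neurophysiologically: larger and earlier visual event-related potentials
(ERPs) to game-relevant target stimuli, and stronger stimulus-locked
alpha-band power. `esporterp` implements an end-to-end analysis pipeline
for such two-group oddball-EEG + cognitive-test expertise studies:

1. a **calibrated synthetic-data generator** that emulates the two-group
   statistical structure (so every downstream stage is testable without
   any recording),
2. **EEG preprocessing** (Kaiser-windowed sinc FIR filters, epoching,
   baseline subtraction, amplitude-based epoch rejection, robust-z channel
   flagging with inverse-distance interpolation),
3. **ERP component measurement** (windowed-extremum peaks, +/-10 ms
   amplitude smoothing, 50% fractional-area latency),
4. **time-frequency analysis** by variational mode decomposition (VMD)
   and Hilbert-Huang spectrograms,
5. **canonical polyadic (CP) tensor decomposition** of space x time x
   trial and space x frequency x time x trial tensors with orthogonal
   spatial factors,
6. a shared **statistical engine**: permutation Welch t-tests, Hedges' g,
   Mann-Whitney U, threshold-free cluster enhancement (TFCE) over 1-D,
   2-D and channel-graph domains, and Spearman correlation maps,
7. **cognitive-test metrics** (reaction-time filtering, correct rates,
   visual-search scores, target-count errors) and **feature-correlation
   analyses** within groups.

The study design it models: two groups of 10 subjects (PRO and NOVICE),
32-channel 10-20 EEG at 250 Hz, four oddball paradigms (a non-specific
blue/red-ball paradigm B/RB and three game-screenshot paradigms BT, MT,
ST with an enemy character of decreasing size), and four cognitive tests
(simple reaction time with mouse and keyboard, choice reaction time,
visual search), plus counted-target errors from the EEG blocks.

# The synthetic-data generator

## What it emulates

`simulate_epochs()` produces epoched EEG whose target trials carry a
P200-N200-P300 component structure calibrated to the published group
statistics (`erp_reference_stats()`), and `simulate_cognitive_log()`
produces trial logs calibrated to `cognitive_reference_stats()`. The
generator's defaults are the study conditions: paradigm timing and trial
counts from the shipped paradigm table, 10 subjects per group, and a 2x
alpha-power scale for the PRO group.

The component waveform is a monotone cubic Hermite interpolant (an
in-package Fritsch-Carlson implementation; we found `stats::splinefun`'s
`"monoH.FC"` mode is not reliably monotone between knots with strongly
asymmetric flanking slopes, and an overshoot plants spurious extrema)
through extremum knots: a zero pre-stimulus baseline, a 60 ms rise into
the P200 peak, the N200 trough, the P300 peak, and a 100 ms decay. When
the N200-P300 gap is wide (the late, "nominal" P300 of the ST paradigm)
a small recovery hump and valley are inserted so the late positivity is
a localized peak, as in real visual-search ERPs. The N200 is a genuine
trough *riding on surrounding positivity* -- its planted value is the
(typically positive) signal value at the trough, which is how the
reference table reports N200 amplitudes.

Because the reference amplitudes and latencies are themselves *measured*
quantities (smoothed peak amplitude; fractional-area latency), planting
them requires inverting the measurement. A per-subject self-calibration
loop adjusts the knots (decaying-step fixed point, 40 iterations,
best-iterate kept) until the measured values of the noiseless waveform
equal the drawn targets. On low-noise data this achieves per-subject
recovery well within 0.5 uV and 8 ms (typically < 4 ms).

Between-subject variability: component parameters are drawn once per
subject from the group profile; each trial adds Gaussian jitter with 1/3
of the between-subject SD. Draws are clamped to the physiological shape
(peaks positive; the N200 trough at least 1 uV below both peaks), and
the hump/valley branch is decided once per subject so that trial jitter
cannot mix different waveform geometries into a smeared average.

All epochs carry 1/f background noise (normalized per-trial RMS,
spectral exponent 1, default 5 uV) and a posterior ~10 Hz alpha
oscillation with per-trial random phase and frequency (SD = bandwidth/2)
and per-subject lognormal amplitude variation (sigma = 0.15). The
component topography is a posterior Gaussian pattern (45 mm spatial
scale) normalized so its mean over the P3/Pz/P4/PO3/PO4 ROI is exactly
1, making ROI-averaged measures directly comparable to the planted
values; the alpha topography is broader (80 mm), so occipital alpha is
clearly visible at Cz, as in real EEG.

Reaction times are shifted lognormal (100 ms shift) matched to the
profile mean/SD; correctness is Bernoulli; visual-search times are
lognormal per condition; counted targets derive from a Gaussian count
error. A configurable fraction of trials (default 2%) is replaced by
out-of-threshold reaction times to exercise the filtering stage.

## What it does not emulate

No continuous recordings, no ocular/cardiac artifact morphologies, no
eye movements, no trial-order or fatigue effects, no cross-subject
topography differences, and no dependence structure between a subject's
EEG and cognitive scores (features are drawn independently, so
pipeline-level correlation analyses on default synthetic data test the
machinery, not a planted brain-behavior link). Passing tests therefore
demonstrate correctness of the measurement and inference chain under a
known generative model, not performance on real recordings.

# Measurement choices

**Component windows.** P200 150-250 ms (positive), N200 200-320 ms
(negative), P300 280-450 ms (positive); for ST the P300 window is
350-800 ms, because with a demanding search stimulus the maximal
positive deflection occurs long after 300 ms. The manual peak-validity
inspection of the original workflow is replaced by an automatic
windowed extremum plus a validity flag (extremum on a window edge, or
no area of the correct polarity).

**Amplitude** is the mean of the signal within +/-10 ms of the detected
peak (ties in flat tops resolve to the middle of the tied run).

**Fractional-area latency** is the earliest time at which the cumulative
area under the rectified peak reaches half the total, computed on the
piecewise-linear signal with sub-sample interpolation. Integration runs
between the nearest flanking local extrema around the peak (separating
overlapping neighbors inside wide windows), and the rectification
reference is the higher of the two flanking saddle levels -- never below
zero for positive components, so an isolated bump on a zero baseline
reduces to the classic clip-at-zero rule. For negative components the
dip area below the flanking ridge is integrated, which keeps the measure
defined for troughs riding on positivity. These refinements matter: with
plain clip-at-zero integration over the whole window, a component riding
on a pedestal inherits the pedestal's area and its latency estimate is
biased by >8 ms.

# VMD and Hilbert spectrograms

`vmd()` implements the frequency-domain ADMM scheme: Wiener-filter mode
updates, power-weighted center-frequency updates, optional dual ascent
(`tau`; default 0, noise-tolerant), mirror extension to twice the signal
length. Defaults: K = 6 modes, bandwidth penalty alpha = 2000,
convergence tolerance 1e-7, center frequencies initialized uniformly
over 0-30 Hz. Two practical notes: with an over-specified K a lone tone
can split across duplicate center frequencies (the band is still
isolated -- the test suite checks the joint energy of near-tone modes),
and reconstruction error concentrates at epoch edges, which is why
spectrograms are cropped to -100..+500 ms before statistics.

`hilbert_spectrogram()` bins each mode's squared instantaneous amplitude
at its instantaneous frequency (derivative of unwrapped phase, 5-sample
median filter against unwrap spikes) into 101 bins over 0-30 Hz.
Out-of-range instantaneous frequencies are clipped and counted.

`compare_group_spectrograms()` offers two exchangeability units. The
default, `"subjects"`, averages per-trial spectrograms within subject
and permutes subject labels: conservative and respectful of
between-subject variance. The `"trials"` mode pools and permutes
single-trial spectrograms, matching the common practice of comparing
mean spectrograms over all trials; it is far more sensitive (at the
study's scale the subject-level test cannot resolve a 2x alpha-power
difference through a family-wise max-statistic correction, while the
trial-pooled test shows a large contiguous significant alpha region) but
its p-values ignore the subject level. The methods report should state
which mode produced a given map.

# Tensor decompositions

`build_order3()` pools the retained target epochs of both groups,
removes a per-trial offset estimated from the first 80 ms, and crops to
-100..+900 ms (251 samples at 250 Hz). `build_order4()` stacks per-trial
Hilbert spectrograms of one or more channels (optionally restricted to
3-30 Hz to suppress dominant low-frequency ERP energy).

`fit_cpd()` is alternating least squares with an orthonormality
constraint on the spatial factor, imposed each sweep by the polar
projection (SVD) of the unconstrained update -- this prevents the
degenerate, diverging component pairs unconstrained CPD is prone to on
EEG data. Component scale is absorbed into the trial factor; components
are ordered by explained energy and sign-aligned so each temporal
factor's extremum is positive (resolving CPD's permutation and sign
ambiguities deterministically). Defaults: convergence at 1e-8 relative
fit change, at most 200 sweeps, 5 random restarts keeping the best fit;
rank 5 mirrors the reference analysis, and the heavier verification runs
use 2 restarts (documented per call). Rank-deficient normal equations
fall back to a ridge-regularized solve with a warning.

Per-subject component power is the *signed* sum of the subject's
trial-factor coefficients (an absolute-sum mode exists behind a flag);
after sign alignment a component present in every trial has
predominantly positive coefficients, so the signed sum scales with
component strength. Group differences use the exact Mann-Whitney U test
(<= 10 subjects per group, untied).

# Statistical engine

**Permutation Welch tests.** Two-sided label permutation of the
unequal-variance t statistic; exact enumeration whenever the number of
distinct assignments does not exceed the permutation budget, otherwise
uniform random assignments with the add-one rule. Calibration is
verified empirically (type-I error within [0.03, 0.07] at alpha = 0.05
over 1000 null simulations).

**Hedges' g** uses the exact gamma-function small-sample correction.

**TFCE** integrates cluster extent^E x height^H over thresholds
h = dh, 2dh, ... (E = 0.5, H = 2, dh = max/100 by default); one compiled
kernel serves 1-D time courses, 2-D frequency-time lattices
(4-connectivity) and the channel graph. Signed maps are enhanced on each
polarity separately. Family-wise p-values come from the maximum enhanced
statistic under label permutation, with dh frozen from the observed map.
The pointwise Welch t maps carry a small pseudo-t variance floor (1e-3
of the map-average pooled variance, fixed across permutations): without
it, map points with near-degenerate variance -- rarely-hit spectrogram
bins -- produce unbounded t values that dominate both the enhancement
and its null.

**Channel adjacency** connects electrodes within 75 mm of projected
scalp distance on the shipped 92 mm-radius montage (2-8 neighbors per
channel, none isolated; a 40 mm radius would leave most of a true-scale
10-20 montage disconnected).

**Spearman correlation maps** rank-transform once and permute the scalar
across subjects; ties use mid-ranks; constant columns are flagged NA
rather than erroring.

# Cognitive metrics

Per-subject filtering applies the validity thresholds first (RTM/RTK
120-500 ms, RTD 140-700 ms) and then a 1.5-IQR fence on the survivors;
the fence applies to reaction-time metrics only, not to per-subject
"complex" values (correct rate, final score, count error), which enter
group tests with one value per subject. Trial-level metrics pool the
surviving trials of all subjects. A summary-statistics entry path
(`compare_group_summary()`) reproduces the published group statistics
from mean/SD/n alone; with matching moments it agrees exactly with the
raw-data path for t and g.

# Correlation analyses and the two-part significance criteria

`build_feature_table()` assembles one row per subject of one group: the
24 combined ERP features (mean over Fz/Cz/Pz of each component's
amplitude and latency, per paradigm), the cognitive features, and (PRO
only) hours in game. Intragroup analyses never mix groups. With 10
subjects per group, topographic correlations are only trusted when (1)
the pattern is consistent across closely related paradigms --
operationalized as sign concordance of the summed rho over the union of
significant channels for the default pair MT/ST -- and (2) at least two
significant channels share an adjacency edge. Both operationalizations
are configurable; the concordance rule is our quantitative rendering of
an informally stated criterion.

# Problem sizes used in verification

The shipped test-and-verification runs use: full-scale CPD recovery on a
32 x 251 x 800 rank-3 tensor; 20 seeded replicates of 16 x 60 x 400
rank-2 tensors for power scoring; 1000 null simulations x 2000
permutations for test calibration; 20 seeded replicates of the full
10-per-group MT paradigm for ERP group detection; and one B/RB
spectrogram comparison at the full study size (10 subjects per group x
60 target trials).
The parameter-recovery check runs at low noise (0.25 uV) to isolate
systematic bias from estimator variance.

# Known limitations

- The ST-paradigm P300 latency (a maximal-deflection measure over a
  450 ms window, with the largest between-subject SDs in the reference
  table) has intrinsic two-sample power of only ~90% at 10 subjects per
  group -- a property of the study configuration itself, not of the
  implementation -- and its fractional-area estimate is the most
  noise-sensitive of all measures. Group comparisons on MT are the
  robust demonstration case.
- Subject-level spectrogram inference with family-wise TFCE correction
  is strongly conservative at n = 10; the trial-pooled mode trades
  subject-level generalizability for sensitivity.
- VMD mode duplication with over-specified K is not merged
  automatically.
- The generator draws EEG and cognitive features independently, so it
  cannot validate brain-behavior correlation *effect sizes*, only the
  correlation machinery's calibration.
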