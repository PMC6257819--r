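---
title: "Decoding hierarchical serial-order control codes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding hierarchical serial-order control codes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(oscdecode)
```

## The problem

When people produce a memorized sequence, classical theory holds that
behavior is organized by abstract, content-independent control codes: which
basic element is due, which ordinal slot it occupies inside its chunk,
which chunk is active, and where that chunk sits in the larger plan. In the
cycling-sequence paradigm, participants repeatedly step through a
pre-learned sequence of line orientations (45/90/135 degrees, coded A/B/C),
grouped into 3-element chunks, and verify a probe orientation on every
trial. Because every element, within-chunk position, chunk identity and
chunk position combination occurs equally often across blocks, the four
codes vary orthogonally and can be decoded from multichannel EEG
independently of one another.

`oscdecode` implements this entire analysis chain as a tested pipeline and
pairs it with a synthetic-data generator that embeds known control codes in
oscillatory EEG. Every stage is validated by recovery: what the generator
injects, the analysis must find, and nothing else.

## Task model

`experiment_design()` encodes two design families. The 3-chunk pool
(variants `exp1`/`exp2`) yields the 6 orderings of {ABC, BCA, CAB}; 24
blocks of 6 cycles of a 9-element sequence give 54 trials per block. The
6-chunk pool (`exp3`) forms two-chunk sequences under a no-element-repeat
rule at chunk junctions. The rule is applied *cyclically* — including the
junction from the last chunk back to the first, because sequences wrap
within a block. Under the cyclic reading the enumeration yields 12
sequences; without the wrap-around junction it would yield 18. We adopted
the cyclic rule because it is the only reading consistent with the design's
stated sequence count, and the enumeration is cross-checked against brute
force over all 30 ordered chunk pairs in the test suite.

Other design-level choices that the task description leaves open:

* probe match probability defaults to 0.5 (`assign_probes()`);
* the WM capacity median split assigns at-median subjects to the low group
  (configurable), since some tie policy must be fixed for reproducibility;
* sequences are enumerated in lexicographic order of chunk labels so golden
  tests are stable.

Working-memory capacity is summarized by Cowan's K = S(H − F) from a
change-detection task with set sizes 4 and 8 (`cowans_k()`).

## Synthetic EEG generator

`simulate_eeg()` builds each trial as 1/f^β background noise plus one
band-limited oscillation per control code:

* **Noise.** Per-channel spectrally shaped Gaussian noise (default β = 1,
  RMS 10 µV) with a common component across channels (default correlation
  0.2). These values are in the range typically reported for ongoing scalp
  EEG and make the default decoding problem genuinely noisy.
* **Carriers.** Each code's oscillation is a sinusoid with random phase per
  trial and per-trial frequency jitter across its band — simpler and more
  spectrally controllable than filtered noise, and sufficient because the
  analyses operate on instantaneous power.
* **Topographies.** Each code instance has a unit-norm spatial weight
  vector over the 20-channel montage, drawn from a seeded standard normal
  with a minimum pairwise angle of 30 degrees, so separability is governed
  by amplitude rather than chance geometry.
* **Placement.** By default elements live in the alpha band (8–12 Hz)
  during the probe period (0–300 ms), chunk identity in alpha during late
  preparation (−600–0 ms), within-chunk positions in theta (4–7 Hz) during
  preparation, and chunk positions in theta during the probe period — the
  band assignments where each code was most clearly expressed in human
  data, arranged over disjoint band-by-window regions so each code's
  recovery can be scored independently.
* **Epochs** span −1250 to +700 ms around probe onset (the longest
  preparation period plus the response window) and are generated with
  500 ms of padding per side, beyond 3 standard deviations of the slowest
  wavelet, so convolution edge effects never touch analyzed samples.

What the generator deliberately does **not** emulate: volume-conducted
source geometry, event-related transients, autocorrelated artifacts,
between-trial carryover, non-stationary noise, or realistic electrode
covariance. Passing recovery tests therefore demonstrates that the
analysis code is correct and calibrated — not that the pipeline's
sensitivity on real recordings matches any particular human effect size.

Behavior is simulated per trial (`simulate_behavior()`): log-normal RTs
with an additive chunk-boundary cost at within-chunk position 1 (default
14 ms on a 450 ms base, trial SD 150 ms), Bernoulli errors with a boundary
cost (default 3.8 points on a 5% base), a WM-group scaling of boundary
effects (default 2 for low-capacity subjects), an optional linear coupling
of log RT on a per-trial evidence covariate, and, for the self-paced
variant, retrieval times with a large (372 ms) boundary cost.

## Preprocessing and time-frequency decomposition

`reject_artifacts()` screens trials with the recording-level rules:
peak-to-peak above 80 µV in 200 ms windows stepped by 50 ms (blinks, on
frontal channels standing in for a VEOG lead), a flat-line detector
(total range at most 0.1 µV over 200 ms — the "blocking" criterion read as
a total-range rule) and a step detector on a horizontal channel pair. The
original eye-movement criterion is gaze-based (1 degree) and requires
calibration data that synthetic EEG does not have, so the package
substitutes a documented 40 µV step threshold, configurable. The blocking
detector steps by 10 ms so that a flat segment no longer than its own
window cannot fall between window positions.

`wavelet_bank()` builds 32 log-spaced frequencies from 4 to 35 Hz whose
cycle counts rise linearly from 3 to 10 over the bank index (equivalently,
linearly over log frequency — the interpolation rule must be fixed and
this is the simplest), with temporal width σ = n/(2πf). `tf_power()`
convolves per trial and electrode in the frequency domain (FFT, one-sided
Gaussian kernel with unit gain at the wavelet frequency and doubled
analytic part, inverse FFT) and returns squared magnitude. A pure
sinusoid of amplitude a at a bank frequency therefore has power a² there,
which the tests check against an independent time-domain convolution.
Average re-referencing is available (`avg_reref()`) but not applied by
default to synthetic data, whose generator has no reference structure.

## Frequency-by-time decoding

For every (frequency, time) cell, `decode_map()`:

1. partitions trials into 4 folds, equating counts per class within and
   across folds by randomly dropping surplus trials;
2. averages power over trials per fold and class with a centered 25-sample
   (100 ms at 250 Hz) sliding window;
3. z-scores the averaged values across electrodes per class, frequency and
   time point (population SD; a zero-variance cell maps to zeros), which
   removes spatially uniform effects;
4. trains a shrinkage-regularized linear discriminant on three folds'
   class rows and tests on the held-out fold's rows, rotating folds and
   repeating the whole procedure with fresh partitions (default 30
   iterations; reduced sizes are used in examples and tests).

Test-fold observations are built by the same averaging/z-scoring transform
computed within the test fold; no parameters are transferred from training
folds, mirroring the fold-wise construction of the analysis this package
implements. With 20 electrodes and only a dozen averaged observations,
plain covariance estimates are singular, so the discriminant shrinks the
pooled covariance toward a scaled identity with a Ledoit–Wolf intensity
("automatic shrinkage"); a fixed intensity can be supplied, and with
shrinkage 0 the classifier agrees with a reference LDA implementation in
the tests. Posteriors are clipped to [1e−6, 1−1e−6] before logit so
degenerate posteriors cannot produce infinities. A single master seed
spawns per-iteration streams, making every drop and partition
reproducible.

Confusions are accumulated per cell as column-stochastic matrices
(columns = true class). Per-trial evidence — the logit posterior of the
trial's correct label, averaged over the iterations in which the trial was
held out — is computed by `decode_patterns()` on band/period-reduced data
(`band_period_power()`), which is where evidence enters the RT model; the
full-map decoder skips it for speed. `decode_conditional()` decodes a code
per stratum of another variable, either training on all strata and testing
within each (the mode used to ask whether chunk information recurs across
within-chunk positions) or training within strata.

Window centers default to every sample; a `window_step` of 10–15 samples
is used in examples and tests, which decimates the time axis without
changing any single cell's computation.

## Cluster-based permutation inference

`cluster_permutation()` tests group maps against chance: one-sample
t-values per cell, entry threshold t > 2.0 exactly as specified (not
recomputed from α and df), 4-connected clusters over the
frequency-by-time grid (no diagonal adjacency), cluster mass = sum of
t-values, and a max-mass null built by randomly sign-flipping each
subject's deviation map — the standard one-sample permutation scheme that
group-level label shuffling reduces to for accuracy-versus-chance tests.
Cluster p-values use the (b + 1)/(m + 1) correction, one-sided. Defaults:
1000 permutations (warning below 100). Because the null has only 2^n
distinct sign patterns, cluster significance below 0.05 requires at least
five subjects; the analysis scripts use six or more.

The suite verifies the component labeling against an independent
propagation algorithm, checks the family-wise error rate over 500 null
replicates, and checks that injected rectangular effects are recovered
with Jaccard overlap of at least 0.5.

## Generalization, RSA, and chaining

`cross_classify()` trains position decoders on all but one instance of a
generalization variable (e.g. two of three elements) and tests on the
held-out instance; reference scores apply the same decoders to equally
sized held-out subsets of the training instances, so both scores rest on
identically sized test sets — without the matching, reference scores would
be inflated simply by having more data.

`build_model_matrix()` provides the theoretical confusion models
(discrete, unique-position-1, the 9-class element/position/conjunction
set, and the lagged-element set), all column-stochastic by construction.
`fit_rsa()` regresses logit-transformed confusion cells (clipped at 1e−4;
all cells including the diagonal) on all model predictors simultaneously
in a mixed model with per-subject random intercepts and slopes, falling
back to per-subject least squares plus group t-tests when the mixed fit
fails; the path taken is recorded. Predictors enter as raw 0/0.5/1 cell
values (standardization optional) so coefficients stay on the logit scale
of the criterion.

`chaining_test()` computes, per within-chunk transition A→B, the Fisher-z
difference cor(A_late, B_early) − cor(A_early, B_late) from electrode
patterns of band/period power estimated separately in the first and second
half of a subject's blocks (the session split must be fixed somewhere; the
half split is the default and configurable). Under anticipatory drift of
an element's representation toward its successor the difference is
positive; identical halves give exactly zero.

## Behavior and brain–behavior models

`apply_exclusions()` flags (never deletes) error trials, post-error
trials, RTs under 100 ms and — in the self-paced variant — retrievals over
8000 ms. `structure_contrasts()` evaluates the two orthogonal
within-position contrasts (1 vs 2&3; 2 vs 3) as subject-level contrast
t-tests, reporting F = t² for the 1-df repeated-measures equivalence, plus
a boundary-by-WM-group interaction and Cousineau–Morey within-subject CIs
for plotting. `residualize_rt()` removes the trial/block linear and
quadratic trends, both position contrasts and probe match status from log
RT per subject; `evidence_rt_model()` then fits residual RT on alpha-band
element evidence and theta-band position evidence with random intercepts
and slopes per subject (normal-approximation t-values; two-stage fallback
recorded when the mixed fit fails). `wm_decoding_comparison()` compares
decoding summaries between WM groups per code and tests the code-level
(chunk vs element) by WM-group interaction as a two-sample t on
per-subject differences.

## Problem sizes and reproducibility

The package's own validation uses reduced but faithful sizes chosen to
keep each property measurable: cohorts of 4–12 synthetic subjects with 2–4
blocks for EEG stages (behavioral recovery uses the full 30-subject,
24-block design), 6–8 wavelet frequencies, 2–4 decoding iterations with
window steps of 12–25 samples, and 200–500 permutations or replicates for
the inferential checks. Every stochastic stage takes an explicit seed, and
fixed seeds make all reported numbers bit-reproducible. Arrays at rest are
serialized as `.rds` with axis metadata and all tables as delimited text;
`read_epoched_tsv()` provides a plain-text ingestion route for real
epoched recordings with a channel-name mapping.

## Known limitations

* The generator's oscillatory codes are stationary within their windows;
  drifting or bursty codes are only modeled where a test injects them.
* Eye-movement screening is a voltage step detector, not a gaze criterion.
* Cluster inference assumes exchangeable subject deviations; with fewer
  than ~6 subjects its resolution is limited by the sign-flip null.
* The mixed models use normal-approximation t-values rather than degrees-
  of-freedom corrections.
* Decoding accuracy values obtained on synthetic data characterize the
  pipeline, not human effect sizes.
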