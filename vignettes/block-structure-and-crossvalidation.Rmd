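---
title: "Block structure, temporal dependencies, and what cross-validation really measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Block structure, temporal dependencies, and what cross-validation really measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Passive brain-computer interfaces (pBCIs) estimate implicit user states —
most prominently mental workload — from EEG. Because conditions in such
experiments are delivered in long blocks rather than randomized trials,
samples recorded close together in time share condition-unrelated
structure: electrode gel dries and caps shift, arousal and drowsiness
drift, the aperiodic (1/f) background changes. When a cross-validation
scheme splits non-overlapping windows of such data without respecting the
block structure, windows from the same block end up on both sides of the
train/test split, and a classifier can exploit block identity as a proxy
for the class label. The reported accuracy then mixes genuine class
information with leakage, and — crucially — the amount of inflation grows
with the number of data-dependent fitting steps in the pipeline, so even
the *ranking* of classifiers can change with the evaluation scheme.

`neurocv` implements this whole argument as a reproducible simulation
pipeline: a synthetic generator of block-structured EEG in which class
effects and block confounds are controlled independently, a harmonization
preprocessing chain, four classification pipelines of increasing
complexity, four cross-validation schemes of increasing optimism, and the
statistics used to compare them.

## The synthetic generator

`synth_params()` / `generate_subject()` produce continuous multichannel
recordings (microvolts, 500 Hz, 28-channel 10-20 montage) laid out on one
of four block designs (`make_layout()`):

* `shin_like` — 3 sets, each interleaving 3 runs x 2 conditions of 40 s
  with no condition twice in a row (120 s per condition per set);
* `schroeder_like` — 3 sets, one 140-s run per condition, random order;
* `hinss_multiday_like` — 3 day-sets; within a day all repetitions of a
  condition are grouped into one block of three 32-s runs (96 s per
  condition per set);
* `hinss_singleday_like` — the first day only, with the i-th repetition
  of every condition block forming set i.

The signal model superimposes:

1. **Class-linked oscillators.** A 6 Hz "theta" and a 10 Hz "alpha"
   band-limited Gaussian source, mixed through per-subject random but
   spatially smoothed orthonormal topographies. The high-workload
   condition multiplies theta by `1 + class_effect` and divides alpha by
   the same ratio (workload raises frontal theta and suppresses alpha).
   `class_effect = 0` makes the labels exchangeable given block identity,
   which the test suite verifies with a permutation test.
2. **Block confounds** ("temporal dependencies"), three independent
   mechanisms: a sensor-shift analog (a spatially smooth multiplicative
   channel-gain field *and* a small random rotation of the projection of
   the neural signal onto the cap, both scaled by `channel_gain_sd` — a
   displaced electrode sees a re-projected field, not just a rescaled
   one), a multiplicative random-walk drift on the source amplitudes that
   persists across the runs of a block (drowsiness analog), and a
   per-block offset of the aperiodic 1/f exponent (arousal analog). Each
   is drawn hierarchically — a dominant component per set (share 0.8) and
   a remainder per block — so windows within a set resemble each other
   more than windows across sets, which is exactly the structure that
   leaks, while individual runs remain identifiable. The purely
   multiplicative gain field alone turned out to be insufficient: the
   z-scored LDA pipelines absorb gain changes almost completely, so
   block-respecting and block-ignorant schemes did not separate the way
   nonstationary recordings separate them; the rotation component is what
   makes cross-set transfer genuinely hard for spatially specific
   features.
3. **Between-subject heterogeneity.** Lognormal per-subject factors on
   the oscillator amplitudes (`amp_sd` 0.25) and on the block-confound
   magnitudes (`block_sd` 0.35): cohorts contain easy and hard subjects,
   as real ones do, which is what gives the bootstrap intervals a
   realistic width.
4. **Background noise.** Pink noise whose 1/f shaping plateaus below
   1 Hz, mixed across channels through the symmetric square root of a
   Gaussian spatial kernel (`spatial_rho`, head-radius units) as a
   volume-conduction analog, plus channel-independent white sensor noise.
   Pink and band-limited sources are scaled by their *analytic* output
   standard deviation; normalizing by the realized sd would pin every
   run's total power and induce artificial anti-correlations between the
   windows of a run.

Defaults (28 channels, 500 Hz, theta/alpha source amplitudes 20/28 uV
against a 6 uV pink floor and 0.5 uV white noise, channel-gain sd 0.08
with rotation angle 0.3 rad per unit gain sd, drift sd 0.12,
aperiodic-shift sd 0.12, `spatial_rho` 0.55) were fixed
once so that, after preprocessing, (a) the correlation-based bad-channel
rule removes at most an occasional reference-proximal channel, as in real
harmonized recordings; (b) pseudo-online accuracies sit modestly above
the adjusted chance level; and (c) the block confounds are strong enough
to be decodable (the package's own MDM can predict *set identity* from
covariance matrices above chance when `class_effect = 0`). The magnitude
of real-world temporal dependencies is not identifiable from the
literature; these values are a package design choice, not an estimate.

What the generator does *not* emulate: event-related potentials, ocular
and muscular artifacts, volume-conduction head geometry beyond a 2-D
kernel, between-subject montage differences, and real inter-run pauses
(runs abut in time; gaps exist only as annotation structure). Passing
tests therefore demonstrate properties of the evaluation machinery, not
claims about any specific real dataset.

## Preprocessing

`preprocess_recording()` applies, in a fixed, asserted order: a 50 Hz
zero-phase FIR notch (-6 dB at 49.25/50.75 Hz), a 1 Hz zero-phase FIR
highpass (-6 dB at 0.5 Hz), FFT resampling to 128 Hz, recovery of a
declared online reference via common-average referencing followed by
re-referencing to Pz (whose zero trace is dropped), and removal of
channels whose absolute correlation with the average of their 4 nearest
neighbours (2-D 10-20 geometry) falls below 0.8, computed over the whole
recording.

Numerical choices worth knowing:

* FIR designs are Hamming windowed sincs built by spectral subtraction of
  unit-DC lowpasses, so the applied -6 dB points land exactly on the
  stated edges; filters are linear-phase and applied once with exact
  group-delay compensation (zero phase overall). Filter length follows
  the 3.3/transition-bandwidth rule.
* The notch, highpass and resampler are all diagonal in the frequency
  domain, so the chain applies them in a single FFT pass over a
  reflection-padded signal; this is algebraically identical to running
  the three stages sequentially and is covered by an equivalence test.
* The Butterworth filter banks (canonical delta/theta/alpha/beta for the
  narrowband pipelines; ten 4-Hz bands, 3-25 Hz in 2-Hz steps, for
  FBCSP) select the minimal order meeting a 3 dB passband-ripple and
  10 dB stopband-attenuation constraint with 1 Hz transitions for a
  single pass, and are applied forward-backward (constraints double in
  dB). The zero-phase application is performed spectrally with the
  two-pass magnitude response, which avoids IIR startup transients.
* Windows are 2 s, non-overlapping, aligned to run onsets;
  `floor(duration / 2)` windows per run, trailing remainders dropped.

## Classifiers

All data-dependent fitting (class means, electrode selection, CSP,
normalization, mRMR, LDA) happens strictly on training folds; the
label-independent stages (filtering, windowing, per-window covariances)
are computed once per subject.

* `broad_rmdm` — 1-25 Hz bandpass (-6 dB at 0.5/28 Hz), Ledoit-Wolf
  shrinkage covariance per window, Riemannian minimum-distance-to-mean
  under the affine-invariant metric.
* `narrow_rmdm` — per canonical band: Ledoit-Wolf covariances, backward
  electrode elimination to the 8 channels maximizing the AIRM distance
  between the class geometric means (means estimated once on the full
  set, candidates scored by row/column deletion), block-diagonal
  assembly across bands. Squared AIRM distances add across diagonal
  blocks, so the MDM on the materialized block matrix is computed per
  band and summed — an exact identity the tests assert.
* `psd_lda` — canonical band powers per electrode from the window
  periodogram (bins assigned to `[lo, hi)` by centre frequency; Parseval
  normalization), train-set z-scoring, greedy mRMR to 18 features
  (F-statistic relevance minus mean absolute Pearson correlation with
  the already-selected set), pooled-covariance LDA with equal priors and
  a `1e-9 tr(S)/d` ridge.
* `fbcsp` — per 4-Hz band, 8 CSP filters from the generalized
  eigenproblem of the trace-normalized class covariances (4 largest + 4
  smallest eigenvalues, which lie in (0, 1) for this formulation),
  log-variance features (80 in total), mRMR to 18, LDA.

The Karcher (geometric) mean iterates the standard fixed point from the
arithmetic-mean start with unit step; `geometric_mean()` defaults to a
gradient tolerance of 1e-8 (at most 50 iterations). Inside the pipelines
the class prototypes are iterated to 1e-4 and the electrode-selection
means to 1e-3: both are several orders of magnitude below the statistical
uncertainty of a mean estimated from at most a few hundred windows, and
the discrete channel choice is insensitive at that scale; the looser
tolerances keep the full experiment tractable on one CPU. The mRMR
variant is the continuous F-test/correlation difference criterion; the
original formulation is mutual-information based, so selections can
differ on data with strongly non-linear class dependence. PSD features
use raw (not log) band power.

## Cross-validation schemes and chance levels

* `plan_pseudo_online()` — train on the chronologically first set only;
  each remaining set is a separate test fold (reported separately and
  averaged). Mimics calibrate-then-use deployment.
* `plan_leave_one_block_out()` — one fold per set.
* `plan_sequential_kfold()` — stratified 10-fold; within each class,
  chronologically consecutive windows are assigned to consecutive folds
  (no shuffling), class counts per fold balanced to within one.
* `plan_randomized_kfold()` — as above after a seeded shuffle; the worst
  case for temporally dependent data.

Every plan is validated structurally (disjointness, partition, set
purity, stratification). `adjusted_chance()` is the binomial
`1 - alpha` quantile of a guessing classifier divided by the test size
(e.g. 69/120 = 0.575 for 120 two-class windows): the smallest accuracy a
guesser exceeds with probability below `alpha`.

## Statistics

`bootstrap_scheme_differences()` computes percentile bootstrap CIs
(10,000 iterations, 15 units per draw) of within-unit accuracy
differences between each scheme and pseudo-online, resampling
subject-by-contrast rows pooled across contrasts (and layouts, when
several are present). Percentile rather than BCa intervals are used;
with 15-unit draws their finite-sample coverage runs slightly short of
the nominal 95%, which the coverage test documents. `friedman()` wraps
the standard rank test; `durbin_conover()` implements Conover's rank-sum
t statistics on `(n-1)(k-1)` degrees of freedom with Benjamini-Hochberg
adjustment across the pipeline pairs; `wilcoxon_signed_rank()` wraps the
paired two-sided test (exact for up to 25 non-zero differences).

## The experiment and what it shows

```{r}
library(neurocv)
cfg <- experiment_config(seed = 20260926, out_dir = "experiment-out")
res <- run_experiment(cfg)
res$summary       # mean accuracy per pipeline x scheme
res$bootstrap_ci  # scheme-minus-pseudo-online differences
res$rank_tests    # Friedman + Durbin-Conover pipeline comparisons
```

The default configuration — 15 subjects per contrast spread round-robin
over the shin-like, schroeder-like and hinss-multiday layouts (three
synthetic "datasets", as the statistics pool over datasets), low/high
separability realized as `class_effect` 0.2/0.8 — reproduces the
qualitative findings the package exists to demonstrate:
mean accuracies order pseudo-online <= leave-one-block-out <= sequential
k-fold <= randomized k-fold for every pipeline; the bootstrap CIs of the
k-fold inflations exclude zero for all pipelines while the
leave-one-block-out differences do not; and the FBCSP pipeline (most
data-dependent fitting) inflates far more than broadband RMDM (least).
With both `class_effect` and `block_effect` at zero, all four schemes
stay inside the two-sided binomial chance band at the nominal rate.
`label_block_reassignment_diagnostic()` makes the leakage tangible:
after flipping the labels of half the runs per class, a randomized
k-fold still "classifies" confounded data above chance while the
block-wise scheme drops to chance.

Problem sizes used by the packaged checks: the full comparison runs 30
synthetic recordings (15 per contrast, 720 s each), all four pipelines
and schemes; the null-calibration check uses 24 scaled-down subjects
(20-s runs). Both sizes are package choices that keep a complete run on
a single CPU practical while leaving each fold with the same per-set
window counts as the layouts they emulate.

## Known limitations

* On the grouped layouts (one confound draw per condition per set),
  heavy-confound subjects can show leave-one-block-out *below*
  pseudo-online: training across sets blurs the class prototypes. This
  is part of why the pooled leave-one-block-out differences hover near
  zero, and it mirrors the instability of that comparison in real
  multi-dataset analyses.
* Bootstrap resampling treats subject-contrast rows as exchangeable
  units, as in the original analysis; a hierarchical resampler would be
  more conservative.
* Electrode selection scores candidate removals on submatrices of class
  means estimated once per fold, the computationally light variant of
  the cited method; re-estimating means after every elimination step
  could select different channels.
* All conclusions are about evaluation methodology on surrogate data;
  absolute accuracies have no claim to match any real dataset.
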