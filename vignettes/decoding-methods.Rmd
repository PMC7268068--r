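---
title: "Decoding conditioned threat from voxel patterns: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding conditioned threat from voxel patterns: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fearmvpa)
```

## The scientific problem

In discriminative fear conditioning, one stimulus (CS+) predicts an aversive
outcome (the unconditioned stimulus, US) while a physically similar stimulus
(CS−) does not. A central question is whether sensory cortex merely encodes
the physical properties of the stimuli, or additionally represents the
learned CS–US association itself. Multivoxel pattern analysis (MVPA)
addresses this by asking whether a classifier distinguishes CS+ from CS−
voxel patterns *better* than it distinguishes a matched pair of neutral
sounds (NS1/NS2) that differ physically by the same amount but carry no
threat association. The NS pair is presented in a separate,
instructed-as-safe context; the task design crosses stimulus pair x context
x stimulus complexity.

`fearmvpa` implements this analysis end to end as a simulation-first
pipeline: experimental-design generation, synthetic trial patterns (or full
BOLD time series), beta-series GLM estimation, cross-validated decoding with
a permutation-calibrated chance level, cross-decoding across stimulus
complexity, searchlight mapping, and group-level factorial inference on the
resulting accuracies. The same decoding stages accept real per-trial beta
images (NIfTI) with a mask and an events table.

## Experimental design model

`generate_design()` produces the full chronological trial table. Defaults:
8 blocks of 24 trials in alternating reinforcement/nonreinforcement
contexts; the first half of each block is one stimulus complexity and the
second half the other; within each 12-trial half, the two pair members each
appear 6 times in a seeded random order. Stimuli last 4 s; inter-trial
intervals are drawn uniformly from {7, 9, 11} s. Each of the 8 stimuli is
presented 24 times, and half of the CS+ trials per complexity (12 of 24) are
reinforced by a seeded draw.

Design choices worth noting:

* **Seeded orders rather than a fixed sequence.** Studies often use one
  optimized trial sequence for all participants; the generator exposes the
  seed so both a shared and a per-participant order are possible
  (`fixed_order` in `run_config()`). Sequence optimization for
  design-matrix efficiency is deliberately not implemented — the decoding
  pipeline does not depend on it, and no specific optimization criterion is
  assumed.
* **Counterbalancing flags.** Which context starts block 1
  (`start_context`) and which complexity opens each block (`simple_first`)
  are configuration flags, mirroring between-participant counterbalancing.
* **Reinforced-trial positions** are seeded-random per design; nothing in
  the analysis depends on their placement.
* **Onset bookkeeping.** Onset of trial *k*+1 = onset of *k* + duration +
  ITI; block breaks add a configurable gap (0 in pure simulation).

## Synthetic patterns: what is and is not emulated

`make_pattern_basis()` encodes the hypothesis structure directly. Each of
the four stimulus pairs (context x complexity) receives one
"physical-stimulus" direction `u`; the two pair members sit at `+u` and
`-u`, so every pair is separated by exactly twice the component norm and
CS and NS pairs are exchangeable by construction when the threat amplitude
is zero. The CS pair additionally receives a "threat-association" component
`+v` (CS+) / `-v` (CS−). With `shared_threat = TRUE` the same `v` separates
the simple and the complex CS pair — stimulus-invariant threat encoding
that cross-decodes; with `FALSE` each complexity has an independent `v`.

Default amplitudes (arbitrary units, against `noise_sd = 2` i.i.d. Gaussian
trial/voxel noise):

* `stimulus_amp = c(simple = 1.3, complex = 0.8)` — simple pairs separate
  more than complex pairs, so simple sounds decode better, the qualitative
  complexity effect this design probes.
* `threat_amp = 1.5` — calibrated once so that a simulated group of 20
  participants (the study-scale sample) detects the context main effect in
  at least 90% of replicate groups. This is the "simulated effect size"
  used by the signal-recovery checks.

What the simulation does **not** emulate: spatial noise correlations,
temporal autocorrelation beyond an optional AR(1) flag in time-series mode,
hemodynamic nonlinearity, motion or physiological artifacts, tonotopic
structure, or learning-related drift of the threat pattern over trials.
Passing tests therefore demonstrate the statistical correctness of the
*procedure* (calibration, power at the assumed effect size, geometric
fidelity), not performance on real data, where effect sizes and noise
structure are unknown a priori.

Hemispheres are simulated as independent voxel sets with shared parameters
— the minimal choice compatible with a null hemisphere effect. Voxel
coordinates default to a compact cuboid on a 1.5 mm isotropic grid.

## Beta-series GLM

`build_design_matrix()` implements the single-trial ("beta-series") design:
one HRF-convolved unit-stick regressor per trial, one US regressor per run
(convolved sticks at the US times of the reinforced trials), and a
discrete-cosine high-pass drift set. The HRF is the canonical double-gamma
(delays 6/16 s, unit dispersions, undershoot ratio 1/6, 32 s support),
normalized to unit peak; convolution runs at a microtime resolution of
TR/16 before sampling at scan onsets. The high-pass cutoff defaults to
128 s, giving `floor(2 * duration / cutoff) + 1` cosine columns including
the constant. Run structure for the US regressor defaults to one run per
block-pair, configurable via `runs`.

`estimate_trial_betas()` solves ordinary least squares per voxel through
the singular-value pseudoinverse, so rank-deficient designs degrade to the
minimum-norm solution with a warning rather than failing. Betas of
reinforced trials are estimated like any others but excluded from all
downstream decoding (`retained_trials()`), because US delivery contaminates
their response estimates.

## Decoding with imbalanced classes

The core subtlety of this analysis is class imbalance. Excluding reinforced
trials leaves 24 CS− but only 12 usable CS+ per complexity condition. The
pipeline follows the established procedure:

1. **Z-scoring** (`zscore_across_trials()`): each voxel is standardized
   across all retained trials, once, before any fold split or condition
   subset. Z-scoring over retained trials only (rather than including
   reinforced trials) matches the exclusion rule; an inclusion flag can be
   simulated by passing the full matrix.
2. **Running-index folds** (`make_running_index_folds()`): the *i*-th
   chronological trial of each stimulus is tested in fold *i* mod 3. Every
   fold trains on 24 trials (16 CS−, 8 CS+) and tests on 12 (8 CS−, 4
   CS+), and both training and test data span the whole experiment —
   important because conditioned representations may evolve with learning.
3. **Linear SVM** (`decode_condition()`): linear kernel, cost 1, no class
   weighting — the field-standard MVPA classifier when no hyperparameters
   are reported. A decision value of exactly zero is resolved to the
   training-majority class, a deterministic tie rule.
4. **Permutation chance** (`permutation_chance()`): with a 2:1 training
   imbalance the expected accuracy of an uninformative classifier exceeds
   50%, so a binomial test against 0.5 would be wrong. Chance is instead
   the mean accuracy over label permutations (default 1,000; reduced in
   desk-scale runs) that re-run the *identical* procedure: labels are
   permuted over the retained trials (multiset preserved) and folds are
   recomputed from the permuted labels by the same running-index rule.
5. **Neutral-pair subsampling** (`subsample_ns()`): the safe context has
   all 48 trials usable, so 12 trials of one randomly chosen NS are removed
   to mirror the CS condition's {24, 12} counts. Each permutation averages
   over fresh subsamples (default 100 repetitions); the true-label accuracy
   is averaged over the same number of subsamples, a symmetric
   variance-reduction choice.
6. **Excess accuracy**: raw accuracy minus the condition's own permutation
   chance mean. Chance is computed per condition; pooled summaries are
   reported by the acceptance script for comparison with pooled published
   values.

## Cross-decoding

`cross_decode()` trains on all retained trials of one complexity and tests
on all of the other (disjoint sets, no folds). CS labels are CS+/CS−; the
NS control labels trials by their required key press, matched across
complexity, so motor-response contributions are common to both contexts.
Because train and test sets are disjoint, the permutation null permutes
labels independently within each set, preserving each multiset — the
procedure is otherwise identical to the true-label run.

A numerical caveat documented here because it shaped the test design: when
the threat amplitude is made very large relative to noise, minute
noise-driven misalignments of the training weight vector are amplified by
the large test-set separation, so per-dataset cross-decoding excess under
*independent* components fluctuates substantially even though its
expectation is zero. The property tests therefore check the independent
case on averages over datasets at a moderate signal-to-noise ratio.

## Searchlight

`sphere_offsets()` enumerates all integer grid offsets within the sphere
(boundary inclusive); a 10 mm-diameter light on the 1.5 mm acquisition grid
covers 171 voxels. `run_searchlight()` decodes at every in-mask center
using the sphere-mask intersection (a center with no in-mask neighbors
still uses its own voxel) and subtracts a per-center permutation chance,
with a reduced default of 100 permutations per center for tractability.
`smooth_volume()` offers the conventional Gaussian smoothing
(FWHM-parameterized, mask-aware) for group-space maps; random-field
inference is out of scope.

## Group inference

`factorial_accuracy_model()` decomposes the balanced participant x context
x complexity x hemisphere table of excess accuracies into the seven main
effects and interactions. On a balanced table this is computed as a
repeated-measures ANOVA with per-effect error strata. Satterthwaite
degrees-of-freedom approximations are not reimplemented: under the balance
the pipeline guarantees, each effect's F with df (1, n−1) equals the
squared paired t statistic on per-participant contrast scores (an identity
the tests verify), and the single-factor case coincides exactly with a
random-intercept mixed model. Unbalanced tables are rejected with a pointer
to the mixed-model route rather than silently approximated. Cross-decoding
accuracies are analyzed with factors context (CS vs response-matched NS)
and transfer direction. Post hoc paired comparisons use
`paired_signed_rank()`: exact null for n ≤ 25 (closed form when ranks are
untied, full 2^n enumeration under ties at small n), normal approximation
with tie correction above.

## Numerical choices and degenerate inputs

* Zero-variance voxels are zeroed (with a warning) during z-scoring rather
  than propagating NaN.
* SVM decision-value ties go to the training-majority class.
* Rank-deficient GLM designs use the minimum-norm pseudoinverse solution.
* All-zero paired differences in the signed-rank test return p = 1 with a
  warning.
* Every stochastic step draws its seed from a deterministic chain
  (`spawn_seeds()`) off one master seed, so identical configurations give
  byte-identical result tables and any stage can be rerun in isolation.

## Problem sizes used in the shipped checks

The package's tests and acceptance script run reduced but structurally
faithful configurations, chosen as desk-scale study conditions: groups of
10–20 simulated participants, 30–100 voxels per region, 15–60 label
permutations per condition (with the full 1,000 remaining the analysis
default), 2–3 neutral-pair subsample repetitions, 500–1,000 replicate
tables for calibration rates, and 6^3-voxel volumes for searchlight
localization. The statistical calibration claims (type-I error near 5%,
null excess-accuracy intervals covering zero, ≥90% detection of the
default-size context effect at n = 20) are all recomputed at run time by
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`; this
vignette asserts nothing those runs do not themselves compute.

## Known limitations

* The simulator's i.i.d. noise makes permutation and cross-validation
  assumptions exactly true; real data violate them in ways the pipeline
  does not model (temporal autocorrelation of beta series, session
  effects).
* The searchlight treats the mask as a set of grid points; no surface
  geometry.
* Real-data mode expects per-trial betas already in register with the
  mask; no preprocessing (realignment, normalization, slice timing) is
  provided.
* The factorial model requires the balanced tables the pipeline produces;
  missing cells (e.g., a participant excluded in one hemisphere) need an
  external mixed-model fit.
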