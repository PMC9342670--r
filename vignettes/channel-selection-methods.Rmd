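---
title: "Wrapper channel selection for fNIRS group classification: methods"
author: "fnirsopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wrapper channel selection for fNIRS group classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirsopt)
```

## The problem

Multichannel functional near-infrared spectroscopy (fNIRS) measures
task-evoked changes in oxygenated-hemoglobin concentration over dozens of
cortical sites. A 52-channel montage discriminates patient groups (for
example schizophrenia versus healthy controls during a verbal fluency
task) well, but a smaller montage would make portable, low-cost systems
practical. The question this package addresses is: *which subset of
channels retains the discriminative information?*

This is wrapper feature selection: candidate channel subsets are scored
by the cross-validated accuracy of the downstream classifier itself, and
a metaheuristic searches the $2^D - 1$ non-empty subsets of the $D = 52$
channels. The package implements the complete pipeline — preprocessing,
three feature extractors, seven optimizers with a support-vector-machine
(SVM) fitness, evaluation metrics, and the between-condition statistics —
plus a seeded synthetic-data generator so every stage is testable without
clinical data.

## Signal model and preprocessing

A dataset is a `participants × channels × samples` array of oxy-Hb
signals at a known sampling rate (10 Hz in the reference design, 600
samples covering a 60-s task window), with binary labels (1 = patient,
0 = control, so *sensitivity is patient recall by construction*).

Before time-domain and connectivity feature extraction the signals pass
a 4th-order Butterworth low-pass filter with a 0.6 Hz cutoff, applied
forward and backward. Zero-phase filtering is the fNIRS community
default because phase distortion would shift the task block relative to
the stimulus. The implementation pads each series with 100 samples of
odd reflection at both ends before the forward–backward pass so that
filter startup transients fall in the discarded padding; a constant
signal passes through unchanged to within $1.4\times10^{-7}$ relative.
Wavelet features intentionally use the raw, unfiltered signals, since
the decomposition itself isolates the low-frequency band.

## Feature extraction

Three feature kinds, one matrix of `participants × features` each:

* **Time-domain mean** (`extract_time_mean`): the temporal mean per
  channel over the provided window, then z-normalized per channel across
  participants. The window is used as given — the reference design has
  already cropped to the task block, so no internal cropping is applied.
* **Functional connectivity** (`extract_fc`): Pearson correlation
  between every unordered pair of channel time series, vectorized in
  lexicographic $(i<j)$ order — $\binom{52}{2} = 1326$ features. FC
  features stay on their natural $[-1, 1]$ scale.
* **Wavelet energy** (`extract_wavelet_energy`): a 3-level discrete
  wavelet decomposition with the Daubechies-5 mother wavelet; the
  feature is the energy (sum of squared coefficients) of the level-3
  approximation band, which spans 0–0.625 Hz at 10 Hz sampling — the
  frequency range of the task-evoked hemodynamic response. Energies are
  z-normalized like the time features so that SVM feature scales remain
  comparable across kinds.

Numerical choices worth stating:

* z-normalization uses the **population** (divide-by-$n$) standard
  deviation; the sample convention is available via `sd_type`. The
  choice is immaterial for the SVM (a per-column rescaling) but is fixed
  and tested so results are bit-reproducible.
* The wavelet transform uses **periodization** at the borders. Under
  periodization the decimated analysis bank is orthogonal for any even
  length, so the subband energies partition the total signal energy
  *exactly* (the test suite asserts the Parseval identity to
  $10^{-6}$ relative; in practice it holds to machine precision).
  Zero-padding or symmetric extension would make the partition only
  approximate. Odd-length signals are extended by repeating the final
  sample. A relative-energy variant (approximation energy over total
  energy) is available as an option.
* No wavelet decomposition package for R is part of this package's
  dependency set; the periodized transform is small, self-contained
  (`wavelet_decompose`) and cross-checked in the tests against an
  explicit orthogonal-matrix construction of the analysis operator.

## The classifier fitness

Candidate masks are scored by stratified $k$-fold cross-validation
(default $k = 10$) of an RBF-kernel SVM on the masked feature columns.
For time/wavelet features a mask bit selects that channel's column; for
FC features a pair column is kept only when *both* endpoints are
selected. Design decisions:

* **Kernel**: RBF. The two-parameter $(C, \gamma)$ grid search
  (`tune_hyperparameters`, $C \in 2^{-5..15}$, $\gamma \in 2^{-15..3}$,
  step $2^2$; ties go to smaller $C$, then smaller $\gamma$) implies the
  radial kernel.
* **Frozen hyperparameters during search**: $(C, \gamma)$ are tuned once
  per feature kind on the all-channel matrix and then held fixed for
  every fitness evaluation; the final best mask can be re-tuned. Nested
  per-mask tuning would multiply the cost by the grid size while mostly
  re-ranking ties.
* **One fold partition per run**: all fitness evaluations inside one
  optimization run share the fold assignment drawn from
  `cv_config()$fold_seed`, so fitness differences reflect masks, not
  fold noise.
* **Leakage control**: feature columns are standardized per fold with
  training-fold statistics only.
* **Pooled counts**: out-of-fold predictions are pooled into one
  confusion table (TP, TN, FP, FN); accuracy, sensitivity and
  specificity are the usual ratios in percent, and a zero-denominator
  metric is reported as `NA`, never 0. With equal fold sizes pooling
  coincides with per-fold averaging.

## Encoding and fitness

A candidate solution is a binary mask of length $D$: 1 keeps the
channel, 0 removes it. PSO particles live in $[0,1]^D$ and are
binarized at threshold 0.5 (the boundary value maps to 1; the
published description gives only the threshold, not the boundary side).
An all-zero mask is repaired — PSO sets the bit of the largest position
component, GA sets one uniformly random bit — so the fitness is always
defined.

The objective is

$$\mathrm{fitness} = \mathrm{accuracy}\,(\%) + 0.01 \times \#\{\text{removed channels}\}$$

with accuracy on the 0–100 scale. The removed-channel bonus is at most
$0.51$, strictly below the $0.5$-point accuracy quantum of a
200-participant dataset except in the degenerate 51-zeros case, so it
acts as the intended tie-breaker: among equally accurate masks, fewer
channels win.

## The seven optimizers

All share population size $N = 50$ and 200 iterations by default, and a
memoized fitness cache (identical masks are never re-scored within a
run — a pure cost optimization with no behavioral effect).

**GA** — roulette (fitness-proportionate) parent selection, single-point
crossover with rate 0.8, per-bit mutation with rate 0.01, elitism of
one. The published description fixes the rates but not the operators;
these are the standard choices of the wrapper-selection toolbox lineage.

**PSO** — velocity and position updates per dimension $d$ of particle
$i$:

$$v_{i,d} \leftarrow \omega v_{i,d} + c_1 r_{1,d}(p_{i,d} - x_{i,d}) + c_2 r_{2,d}(g_d - x_{i,d}), \qquad x_{i,d} \leftarrow x_{i,d} + v_{i,d}$$

with $\omega = 0.9$ fixed for all iterations (a single value, no decay
schedule), $c_1 = c_2 = 2$, fresh $r_{1,d}, r_{2,d} \sim U(0,1)$ per
dimension, velocities clamped to $[-0.5, 0.5]$ and positions to
$[0, 1]$ (velocity bounds are prescribed; the position clamp keeps the
encoding domain valid).

**Parallel hybrids pGAPSO-I/II/III** — every generation the merged
population is ranked by fitness and partitioned: variant I sends the
best 50% to GA and the rest to PSO; variant II sends the best 20% to
PSO and the rest to GA; variant III assigns each individual by a fair
coin. Each subpopulation evolves one step with its operator and the
population re-merges, so information is exchanged every generation
(the partition cadence is the open design point; merge-and-rerank is the
reading implemented here). PSO bookkeeping (pbest/gbest) persists across
generations; individuals emerging from a GA step carry position = bits
and velocity 0.

**sPSOGA** — per generation the best half of the population is kept and
updated by one PSO step while the other half is discarded; the kept
particles' pbest positions are binarized and fed to one GA generation
producing $N/2$ offspring; pbest individuals plus offspring form the
next population (pbest retention acts as elitism, so the best-so-far
trace is non-decreasing).

**sGAPSO** — genetic-learning PSO: per particle, a trial exemplar is
built by per-dimension uniform crossover of its pbest with the gbest,
mutated per dimension with rate 0.01 (mutated dimensions are redrawn
uniformly in $[0,1]$), and accepted only if its binarization out-scores
the current exemplar's (a tournament against premature convergence).
The velocity update then uses the single attraction term
$c_1 r (e_{i,d} - x_{i,d})$ in place of the separate cognitive and
social terms. The exemplar operator details follow the genetic-learning
lineage the serial hybrid cites; they are an interpretation, stated
here rather than hidden.

Ranking ties everywhere are broken by higher fitness, then fewer
selected channels, then first-seen order; `brute_force_best` (the
exhaustive oracle used in testing, $D \le 16$) breaks exact fitness
ties by fewer channels then lexicographic order.

Every runner is bit-reproducible from `optimizer_config()$seed`: the
RNG is seeded locally and the caller's RNG state is restored.

## Statistics across conditions

Repeated runs over the $3 \times 7$ (feature × optimizer) design are
summarized per cell (mean ± SD, $n$ runs) and compared with a balanced
two-way fixed-effects ANOVA. Accuracy uses the additive model (the
interaction is pooled into the residual); channel counts use the
interaction model — matching how the two responses behave in the
reference benchmark. Two routes are implemented and must agree
algebraically (a test asserts equality of sums of squares to
$10^{-9}$): `two_way_anova` fits the raw runs via `stats::aov`, while
`anova_from_summary` reconstructs the decomposition from cell means,
SDs and $n$ alone — which is what makes the published per-cell summary
table sufficient input for exact reproduction of the printed $F$
statistics, marginal mean differences, and effect sizes.

Effect size is **partial** $\eta^2 = SS_\mathrm{effect} /
(SS_\mathrm{effect} + SS_\mathrm{residual})$: recomputing from the
bundled reference summaries matches the reported values (0.479, 0.202,
0.562, 0.555) under this definition, so it is the one implemented; the
classical definition would not reproduce them. Pairwise marginal
comparisons use the residual mean square, with Bonferroni adjustment
$p_\mathrm{adj} = \min(1, p \cdot n_\mathrm{pairs})$. Marginal means of
a balanced design are unweighted averages of cell means. Where the
original analysis fell back to bootstrap inference under
non-normality, this package keeps classic ANOVA as the default (the
printed statistics are classic) and leaves resampling to the user.

## The synthetic generator

`simulate_dataset()` emulates exactly the statistical structure the
pipeline assumes, with every constant in `sim_config()`:

* a gamma-shaped hemodynamic impulse response (`hrf`, peak 6 s, zero at
  onset, unit peak) convolved with a task boxcar spanning the window;
* a group effect: patients' task amplitude at the informative channels
  (default {19, 30, 39, 48}, channels that recur across the reference
  benchmark's best masks — the choice is otherwise arbitrary) is scaled
  by $1 - \mathrm{effect\_size}$, default 0.5 — a hypofrontality
  analogue;
* region-shared sinusoidal physiology (Mayer ≈ 0.1 Hz, respiratory
  ≈ 0.25 Hz, cardiac ≈ 1.1 Hz; amplitudes 0.3 / 0.2 / 0.15) whose phases
  are shared within montage regions (`phase_sharing = 0.8`), inducing
  the inter-channel correlation structure the FC features measure;
* linear drift (slope uniform in ±0.3 per window) plus a 0.02 Hz
  sinusoid, and white noise (SD 0.3), with between-participant task
  amplitude variability (CV 0.2).

Amplitudes are in the same arbitrary concentration-change units as the
task response (task amplitude 1); the physiological and noise
amplitudes were chosen once as a realistic mid-range for task-window
oxy-Hb signals and are not calibrated against any particular dataset.

**What passing tests on synthetic data do and do not show.** The
generator produces a cleaner, more homogeneous group difference than
clinical data: the planted effect is identical across patients, noise
is white and Gaussian, and there are no motion artifacts, no deoxy-Hb
channel, and no optode-geometry effects. Consequently all-channel
classification accuracy on the defaults is far higher (≈ 98–100%) than
is realistic for clinical cohorts, and channel recovery is easier.
Tests on this generator validate the *machinery* — that the optimizers
find planted structure, that features measure what they claim — not
clinical performance levels.

## Problem sizes in the test suite

The shipped tests scale the search down from the reference
configuration, a deliberate choice of problem size: the optimizer
oracle checks use $D = 6$ surrogate problems with population 20 and 60
generations against exhaustive enumeration; channel recovery uses the
full 200 × 52 × 600 synthetic default with GA at population 20, 30
generations and 5-fold cross-validation, taking the union of best masks
over 5 seeds. The full-size defaults (N = 50, 200 iterations, 10-fold)
are exercised by the same code paths and remain the package defaults.

## Known limitations

* The channel-to-region montage shipped in `extdata/montage52.csv` is an
  approximate reading of the published probe geometry (region bands on
  a 10/11-channel row grid); it is an editable CSV and users with exact
  optode coordinates should substitute their own.
* Cross-validated wrapper selection reuses the folds that guided the
  search when reporting final accuracy (the default, matching the
  reference procedure); this carries an optimistic selection bias.
  Passing a fresh `fold_seed` to the final evaluation gives the
  unbiased variant.
* The GA/PSO operator details left open by the published description
  (selection scheme, crossover type, hybrid exchange cadence, exemplar
  acceptance) follow the cited toolbox lineages as documented above;
  other readings are possible.
* No motion-artifact correction beyond low-pass filtering, no deoxy- or
  total-hemoglobin processing, no alternative classifiers, and no
  multi-objective formulation.
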