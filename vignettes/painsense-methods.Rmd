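---
title: "Methods: pain-intensity recognition from BVP, ECG and SCL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pain-intensity recognition from BVP, ECG and SCL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the pipeline

painsense implements a complete four-level pain-intensity recognition
pipeline for electrically induced pain, working from three peripheral
channels sampled at 256 Hz: blood volume pulse (BVP, photoplethysmography),
lead-I electrocardiogram (ECG), and skin conductance level (SCL). The four
classes are `L0` (baseline) and `L1`–`L3`, electrical stimulation at
20/30/40 mA spanning a subject's calibrated pain-threshold-to-tolerance
range. The stages are:

1. **Synthetic acquisition** (`simulate_cohort()`): stimulus-locked trial
   generation emulating the protocol — 1-minute trials, 30 sessions per
   subject and day with one trial of every level per session in random
   order (120 trials/subject/day), six subjects, and seven consecutive
   days for one subject.
2. **Preprocessing** (`preprocess_trials()`): per-channel conditioning
   (band-pass, high-pass + moving average + baseline correction,
   smoothing + decimation).
3. **Feature extraction** (`extract_features()`): twelve statistical
   features per channel on sliding 3-s windows over the last 30 s of each
   trial — 10 windows/trial, 36 features/window.
4. **Selection and reduction** (`run_ga()`, `fit_pca()`): a steady-state
   genetic algorithm selects a feature subset by wrapped classifier
   accuracy; PCA then removes residual linear redundancy.
5. **Classification** (`train_classifier()`): one-vs-rest LDA,
   distance-weighted KNN (k = 3), and a soft-margin RBF SVM
   (C = 5, width 2.58).
6. **Evaluation** (`run_scenario()`): single-signal, multi-signal,
   multi-subject, leave-one-subject-out and leave-one-day-out designs,
   with every fitted object (normalisation, GA, PCA, standardisation,
   classifier) fitted strictly inside the training fold.

No public recording of this protocol exists, so the generator is a
first-class, tested component: every downstream stage is exercised against
data whose ground-truth structure is known by construction.

## The synthetic-signal model (and what it does not model)

The generator is a *stated world*, not a physiological simulator. Its aim
is that the four levels differ visibly and statistically in the same
directions a stimulated subject's channels would, with realistic sources
of nuisance variation:

* **BVP**: three harmonics at the subject's heart rate. The amplitude
  shrinks by a factor $(1-a)^r$ at level rank $r$ (vasoconstriction), with
  per-level attenuation $a \sim U(0.08, 0.15)$, and the rate rises by
  $U(3, 6)$ bpm per level (drawn per subject).
* **ECG**: a template P-QRS-T beat train (Gaussian bumps, R amplitude
  1 mV) with 3% inter-beat jitter, the same level-dependent rate, plus
  slow 0.08 Hz baseline wander for the preprocessing to remove.
* **SCL**: tonic level $T \sim U(2, 8)\,\mu S$ plus a stimulus-locked
  exponential phasic ramp $g\,r\,(1 - e^{-t/5\,\mathrm{s}})$ with gain
  $g \sim U(0.3, 0.8)\,\mu S$ per level; the phasic term is exactly zero
  at baseline.
* **Nuisance structure**: additive Gaussian noise per channel (0.5 %refl /
  30 µV / 0.05 µS), trial-to-trial jitter of tonic level (4%), phasic gain
  (15%) and heart rate (2 bpm), and multiplicative day-to-day drift
  (s.d. 5%) on tonic level, pulse amplitude and resting rate.

Effect sizes were chosen once so that the full pipeline separates the four
classes at roughly 85–95% on the pooled six-subject cohort — strong enough
that the headline benchmark is meaningful, weak enough that it is not
saturated — and all are overridable, including a null setting
(`null_effects = TRUE`) that zeroes every stimulus effect. The generator
does **not** model habituation, movement artifacts, electrode drift within
a day, respiratory coupling, or any psychological confound; a green test
establishes that the pipeline's machinery is correct on data with this
structure, not that the headline accuracy transfers to human recordings.
Recovery periods between trials are not synthesised, since all features
are computed inside the 1-minute stimulus windows.

## Preprocessing choices

* The BVP design is a 4th-order Butterworth band-pass with gain 3 and the
  printed cutoffs [30, 200] Hz. That band exceeds the Nyquist frequency of
  256 Hz recordings (and would in any case remove the 1–2 Hz pulse wave),
  so `preprocess_bvp()` implements the printed design verbatim and refuses
  it when the band is not representable, while the pipeline default
  (`default_pipeline_config()`, `extract_features()`) overrides to a
  pulse-preserving 0.5–8 Hz band. We deliberately do not guess what the
  printed band was meant to be.
* Filters are designed by bilinear transform with frequency prewarping
  (so the −3 dB points land exactly on the requested cutoffs; asserted
  against the analytic magnitude response in the tests) and applied in a
  single forward pass. Startup transients are accepted: features use the
  last 30 s of 60-s trials.
* The ECG chain is a 2nd-order 0.5 Hz high-pass, a 50 ms moving average,
  and fiducial-anchored baseline correction: R peaks are detected on the
  smoothed trace, the baseline is sampled at the flattest point between
  consecutive beats, linearly interpolated, and subtracted. The exact
  high-pass order/cutoff and smoothing spans are standard surface-ECG
  practice, not prescribed; all are configurable.
* SCL: 500 ms moving average, then decimation by 2 (to 128 Hz). The
  moving average uses partial windows at the record start so constants map
  to themselves.

## Features

For a window of $N$ samples the twelve statistics are: mean; standard
deviation ($N-1$ divisor); mean absolute first difference and its
standardised form $\theta_1/\sigma$; mean absolute lag-2 difference
($N-2$ divisor) and its standardised form; minimum; maximum; min/$N$;
max/$N$; range; median. Two conventions are fixed here: on constant
windows ($\sigma = 0$) the standardised differences are returned as 0, and
min/$N$, max/$N$ are implemented literally as printed (with $N$ the sample
count), dimensionally odd as that is. Windows are 3 s with a 3-s step over
the final 30 s of each trial, motivated by the latency of the pain
reaction — 10 windows/trial, so one 4-trial session yields a 40 × 36
block and a 30-session subject 1200 × 36. (The stated sample-count range
of 3,840–7,680 for $N$ is inconsistent with 3-s windows; the per-session
40 × 36 count forces 10 windows per trial, so the window's own $N$ — 768
at 256 Hz, 384 at 128 Hz — is used.)

Min-max normalisation is fitted on training rows only and applied to test
rows with the fitted parameters; a constant column maps to 0. Held-out
values may leave $[0,1]$ — that is expected and harmless.

## GA, PCA, classifiers

The wrapper selection is a steady-state GA over 36-bit chromosomes:
roulette-wheel parent selection, standard two-point crossover at rate 0.8,
and per-bit mutation at rate 0.01. The printed description calls the
mutation "Gaussian", which is undefined on binary genes; independent
bit-flips at the printed rate are the standard binary-GA reading and are
what is implemented. The replacement policy (unspecified in the source
design) is: the offspring replaces the current worst individual iff
fitter, which makes the best fitness monotone and gives "best generation"
its natural meaning. One generation is `population_size` offspring events,
so the default 100 × 30 budget bounds fitness evaluations at ≈3,000 plus
initialisation; fitness values are memoised by bit pattern. Fitness is
5-fold stratified LDA accuracy on the selected subset (fold count
unstated in the source design; five is the conventional default), and the
all-zero chromosome scores 0.

PCA is an eigendecomposition of the sample covariance of the GA-selected,
normalised training columns, with eigenvector signs fixed (largest
loading positive) for reproducibility. The retained rank is the smallest
$k$ explaining ≥95% of variance — the source design never states $k$ —
and is overridable.

Classifiers: OvR-LDA uses pooled within-group covariance per binary
problem, ridge-regularised by $10^{-6}\times$ the mean diagonal (the 36
features are partly collinear by construction, e.g. $f_4 = f_3/f_2$).
KNN uses Euclidean distance on standardised features, inverse-distance
weighted votes, a zero-distance override, and ties broken by smaller mean
neighbour distance then label order. The SVM is a soft-margin RBF machine
trained by a Platt-style SMO solver written for this package (no SVM
library ships in the target environment); "width 2.58" is read as the
$\sigma$ in $\exp(-\lVert u-v\rVert^2/2\sigma^2)$, the multi-class
strategy is one-vs-rest to mirror the LDA design, and the optional grid
search covers $C \in \{0.1,1,5,10,100\}$, $\sigma \in \{0.5,1,2.58,5,10\}$
by stratified CV with ties toward smaller $C$ then larger $\sigma$. The
SMO dual optimum is cross-checked against `quadprog` in the tests.

## Evaluation designs and two subtleties

Split scenarios use stratified 75/25 splits at the *window* level, as in
the original design. Two statistical subtleties of that design are worth
recording:

* **Trial-level random effects are shared** between training and test
  windows of the same trial, which flatters absolute accuracies for
  memorising classifiers (KNN especially). This is faithful to the
  replicated design; the leakage guard therefore splits at the trial
  level (`split_groups = "trial_index"`), where windows of one trial stay
  together.
* **Anti-learning under fixed per-subject class totals**: each subject
  contributes exactly 30 trials per class, so a plain class-stratified
  split makes a subject's training and test class compositions negatively
  correlated; on label-free (null) data this biases accuracy several
  points *below* chance. Pooled-data splits therefore stratify by
  subject × level (`strata_col`), which removes the artifact without
  changing expected proportions.

With both in place, the null setting (zero effect sizes, reduced GA
budget, trial-level splits) sits within 3 points of the 25% chance level
for all three classifiers — the no-leakage guard the test suite enforces.
The leave-one-subject-out and leave-one-day-out rotations hold out whole
subjects/days, re-fitting everything per fold; 20 repetitions of the full
LOSO rotation reproduce the repeated between-subject design. The
multi-day rotation restricts to subjects recorded on more than one day.

## Numerical conventions and degenerate inputs

* All randomness derives from one master seed through deterministic
  integer mixing (`painsense:::sub_seed`), so every stage is bit-for-bit
  reproducible; derived seeds stay below $2^{31}$.
* Constant windows, zero-range feature columns, all-zero chromosomes, a
  zero-total roulette wheel (uniform fallback), zero-distance neighbours
  and near-singular covariances all have documented, tested conventions
  rather than errors, except where an error is the only honest answer
  (unknown level labels, band edges beyond Nyquist, classes smaller than
  the fold count).
* The reduced GA budget used by the headline benchmark (population 30,
  10 generations) exists purely for desk-scale runtime; the full budget
  remains the default for `ga_config()`.

## Known limitations

One-vs-rest LDA with argmax scoring is structurally weak when the four
classes lie near a line in feature space (as they do for an ordinal
stimulus variable): the "rest" of a middle class surrounds it on both
sides, so no linear discriminant separates it well and middle levels get
squeezed toward their neighbours. A pooled multiclass LDA does not have
this failure mode, but the one-vs-rest construction is the method
implemented and is reported as such; on the default cohort it trails KNN
and the RBF SVM by a wide margin for exactly this reason.

The headline accuracies of the original human-subject study are not
reproducible from synthetic data, and nothing here claims otherwise: the
package's benchmark asserts only that the full pipeline clears 75% mean
four-class accuracy on its own documented cohort. Single-channel ECG
features are weakly informative in this generator (by design), the SVM
hyperparameters are fixed at the printed values rather than re-tuned per
dataset unless the grid search is enabled, and the evaluation does not
include significance testing between classifiers.
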