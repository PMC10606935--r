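---
title: "Tsallis-entropy screening of insole gait signals: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tsallis-entropy screening of insole gait signals: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitropy)
```

## The problem

Dysfunction of the vestibular system — the inner-ear sensory system for
balance and spatial orientation — degrades the fine regulation of gait.
A subject with a balance disorder still walks with their own habitual
pressure pattern, but the *fluctuation around that habit* grows. This
package implements a screening pipeline that quantifies that
fluctuation from a short walk (~10–15 s) recorded by eight
force-sensitive resistors (FSRs) embedded in shoe insoles, four under
each foot (heel, two metatarsal heads, hallux; channels S0–S3 right,
S4–S7 left), sampled at 20 Hz. Because clinical recordings of this kind
are not publicly distributable, the package pairs the analysis with a
seeded synthetic-cohort generator that reproduces the statistical
structure the analysis relies on, so every stage is testable end to
end.

The pipeline has five stages, each a module of the package:

1. **synth** — simulate cohorts of labelled walk recordings
   (`cohort_spec()`, `generate_cohort()`), plus the FSR voltage/weight
   calibration (`voltage_to_weight()`).
2. **preprocess** — min–max normalization, per-foot ground-contact
   detection, framing (dropping the first and last step), and 20-fold
   shape-preserving cubic Hermite upsampling (`preprocess_walk()`).
3. **detrend** — the adaptive stepwise trend-curve algorithm
   (`detrend_walk()`) and polynomial baselines
   (`detrend_polynomial()`).
4. **entropy** — histograms of absolute residuals, Tsallis entropy,
   and the 16-feature vector (`extract_features()`,
   `feature_table()`).
5. **classify** — a nine-model classifier suite with stratified
   cross-validation and full confusion/ROC reporting
   (`train_evaluate()`).

The numbered scripts under `analysis/` run these stages in order over
the default cohort and leave their tables under `results/`.

## Tsallis entropy

For a discrete distribution $p_1,\dots,p_N$ the Tsallis entropy with
entropic index $q$ is

$$ S_q = \frac{1 - \sum_{i=1}^{N} p_i^{\,q}}{q - 1}, $$

which recovers Shannon entropy $-\sum p_i \ln p_i$ as $q \to 1$. For
two independent systems it is *pseudo-additive*,
$S_q(X{+}Y) = S_q(X) + S_q(Y) + (1-q)\,S_q(X)\,S_q(Y)$, with $(1-q)$
measuring the deviation from ordinary additivity; `tsallis_additivity_gap()`
exposes both sides of this identity and the test suite holds it to
1e-10 on random product distributions. With $q < 1$ rare states are
weighted more heavily than under Shannon entropy, which suits gait
fluctuations: the informative part of the residual distribution is its
spread away from zero. The default $q = 0.82$ is the value at which
class discrimination peaks on the clinical data this pipeline models;
on synthetic cohorts the accuracy-versus-$q$ curve is fairly flat
(see `analysis/05_q_sweep.R`), so the package treats $q$ as a tunable
parameter rather than a constant of nature.

## The stepwise trend algorithm

Let $F_i$ be the (upsampled, normalized) data of step $i$ for one
sensor. The subject's habitual waveform is estimated recursively:
$T_1 = F_1$, and for $i \ge 2$ the previous trend is first scaled to
the current step length by nearest-neighbour interpolation
(`scale_trend()`, giving $\check T_{i-1}$) and then blended:

$$ T_i = \alpha F_i + (1 - \alpha)\,\check T_{i-1}. $$

$\alpha \in [0, \alpha_{\max}]$ controls how fast the trend adapts;
$\alpha_{\max} = 0.23$ by default, a balance between following the
subject's habit and overfitting each individual step. The adopted
$\alpha$ is the smallest value at which the error
$\varepsilon = \operatorname{mean}|T_i - F_i|$ drops below a threshold
(default $10^{-6}$), else the cap. Two numerical notes:

* $\varepsilon$ is interpreted as a **mean absolute** deviation. Read
  without the absolute value the criterion would be degenerate — the
  signed mean of residuals around a blended trend is near zero by
  construction and would terminate the search immediately.
* Because $T_i - F_i = (1-\alpha)(\check T_{i-1} - F_i)$, the error is
  exactly linear in $\alpha$:
  $\varepsilon(\alpha) = (1-\alpha)\,\varepsilon_0$ with
  $\varepsilon_0 = \operatorname{mean}|\check T_{i-1} - F_i|$. The
  smallest admissible $\alpha$ therefore has the closed form
  $\alpha^* = 0$ if $\varepsilon_0 \le \tau$, else
  $\alpha^* = \min(\alpha_{\max},\, 1 - \tau/\varepsilon_0)$, and no
  iterative search is needed. The test suite verifies the closed form
  against a literal fine-grid search on 1000 random step/trend pairs.

The residual $F_i - T_i$ of the first step is structurally zero, so it
is excluded from the entropy features by default
(`exclude_first_step = TRUE`); including it would only inflate the
zero bin of every histogram.

In `scale_trend()` the index mapping rounds half-up. Ties occur only
when `(j * (Lp - 1)) / (Lc - 1)` is exactly half-integral, which is
rare for the step lengths the pipeline produces; the choice is fixed
and documented rather than configurable.

## From residuals to 16 features

Per sensor, samples where the sensor itself is unloaded (normalized
value below `activity_threshold`, default 0.05 and shared with the
contact threshold) are removed — a heel sensor during toe-off carries
no information. The absolute residuals of the remaining samples are
pooled across steps and binned into at most 25 equal-width bins over
$[0, \max]$; the **entire-gait TE** of the sensor is the Tsallis
entropy of that histogram. When fewer than `4 * n_bins` samples are
available the bin count shrinks to `floor(n/4)` (never below 2), so
each bin keeps a workable occupancy.

The **stepwise deviation** feature starts from per-step entropies
$e_k$. Two readings of the step-to-step statistic are possible: apply
the deviation to the $e_k$ themselves (`stepwise_mode = "raw"`) or to
their changes $\Delta_k = e_{k+1} - e_k$ (`"diff"`, the default). The
default follows the motivating argument that for an ideal healthy
walker the *change* of entropy from step to step is zero, which makes
the deviation-from-zero statistic coherent. That statistic,
$\sigma_{E'}$ (`sigma_e_prime()`), expands the set with the negatives
of all its values and takes the population standard deviation of the
expanded set — algebraically the root-mean-square of the input, an
identity the tests hold to 1e-12.

Per-step histograms share their bin edges with the pooled residual
range by default (`per_step_range = "shared"`). With each step binned
over its own $[0,\max]$ range (the `"own"` mode) the per-step entropy
is invariant to the step's fluctuation scale, and the stepwise feature
goes blind to exactly the step-to-step amplitude variability it is
meant to measure — empirically, raising the generator's jitter then
fails to raise $\sigma_{E'}$. Shared edges restore scale sensitivity
(jitter increases $\sigma_{E'}$ in 19/20 seeded replicates, one-sided
sign test p ≈ 2e-5).

Eight sensors × (entire-gait TE, stepwise $\sigma_{E'}$) give the
16-feature row, ordered `S0_te..S7_te, S0_sigma..S7_sigma`. A sensor
with no actively-loaded samples yields `NA` features flagged missing;
the classifier imputes them with training-fold medians.

## What the synthetic generator emulates — and what it does not

Each subject owns a fixed habitual stance profile per sensor: a
flat-topped generalized Gaussian
$a \exp\!\big(-\tfrac12 ((u - p)/w)^{2m}\big)$ over stance fraction
$u$, with heel sensors peaking early ($p = 0.30$), metatarsal sensors
mid-stance (0.45, 0.55) and the hallux late (0.70), and $m = 4$
(`flat`) giving the rapid loading/unloading flanks and rounded plateau
seen in real force-time curves. Stance (0.55–0.75 s) and swing
(0.35–0.50 s) durations are drawn uniformly per step; the left foot is
offset by half a cycle; swing emits small positive noise so contact
detection is non-trivial.

Within stance, the emitted signal is the profile plus stationary AR(1)
fluctuation (coefficient 0.8 — force fluctuations wander rather than
flicker) whose standard deviation is redrawn each step as
$\sigma \cdot e^{s Z}$, $Z \sim N(0,1)$: a lognormal step-to-step
jitter of the fluctuation level. Diseased subjects get
$\sigma = 0.06$ versus 0.02 and a doubled jitter log-sd ($s = 0.70$
versus 0.35). On the under-heel channels S0/S4 only a fraction
`heel_attenuation = 0.3` of the class difference (in both $\sigma$ and
$s$) survives, because even an impaired subject presses the heel down
consistently.

Two structural points deserve emphasis, because they determined the
design:

* The entire-gait TE is computed from a histogram spanning
  $[0, \max]$, so it is **invariant to a pure rescaling** of the
  residuals. A larger fluctuation $\sigma$ alone does not move the
  feature; what moves it is the *shape* of the residual distribution.
  In the generator that shape contrast arises because steps land at
  arbitrary sub-sample phases of the 20 Hz grid: the stepwise trend
  cannot adapt to per-step phase, leaving fixed-amplitude residual
  bursts at the steep profile flanks, shared by both classes. Healthy
  plateau residuals are small against those bursts, giving a peaked
  histogram (low TE); the diseased classes' larger, jittering plateau
  fluctuation fills the mid-range of the histogram (higher TE). The
  flat-topped profile is what localizes the bursts; with round
  (Gaussian, `flat = 1`) profiles the burst envelope smears across the
  whole stance and the class contrast washes out.
* The per-step lognormal jitter is what the $\sigma_{E'}$ features
  respond to, via the shared-edge per-step histograms described above.

What the generator does **not** model: biomechanically faithful gait
(no kinematics, no load transfer between sensors), specific vestibular
diseases or their subtypes, sensor non-linearity and drift,
inter-sensor crosstalk, or fatigue across the walk. Passing tests on
synthetic cohorts therefore demonstrate that the pipeline recovers the
statistical structure it assumes — larger, more variable fluctuation
around a stable habit — not that it reaches any particular accuracy on
clinical recordings.

## Preprocessing conventions and degenerate inputs

* Intervals are 1-based closed integer sample ranges throughout, the
  natural R convention.
* Contact: per foot, a sample is in the air when the maximum of its
  four normalized channels falls below `air_threshold` (default 0.05
  of the normalized range; the level is not critical because swing
  noise and stance force are separated by an order of magnitude, and
  it is configurable). Contact runs shorter than
  `min_segment_samples = 3` are discarded as noise spikes rather than
  counted as steps.
* Normalization happens per sensor. The framed walk is renormalized
  over the span of the retained steps (`normalize_scope = "framed"`),
  so gait initiation/termination cannot stretch the scale; a `"full"`
  mode keeps the whole-record scaling. A constant channel is a
  degenerate input and errors rather than silently producing zeros.
* Upsampling uses shape-preserving piecewise cubic Hermite (pchip)
  interpolation: the refined step passes through every original sample
  exactly (`factor*(L-1)+1` samples from `L`), reproduces linear data
  exactly, and never overshoots the local data range, so normalized
  input stays in $[0,1]$.
* Walks with fewer than three stance intervals per foot cannot be
  framed and error out, as do sensors with fewer than three steps at
  feature extraction (the stepwise series needs at least two retained
  per-step entropies).

## Classification and evaluation

The suite mirrors the model families of point-and-click learner tools:
Gaussian-kernel SVM, logistic regression, cosine-distance KNN with 10
neighbours, a wide single-hidden-layer network (100 units — a
documented stand-in for the proprietary "wide neural network" preset),
a decision tree, kernel-density naive Bayes, quadratic discriminant
analysis, bagged trees (a random forest with `mtry` equal to the
number of features), and a second RBF-SVM implementation. Features are
standardized with training-fold statistics only (cosine-KNN and RBF
kernels are scale-sensitive), and "diseased" is the positive class for
sensitivity, F1 and MCC.

Both 10-fold stratified cross-validation (default) and a single
stratified 45/15 holdout are implemented, since descriptions of this
kind of study often mix the two; `eval_config(scheme =)` switches.
Everything is deterministic given `rng_seed`. ROC curves come from a
plain threshold sweep with tied scores grouped, AUC by the trapezoid
rule; the implementation is cross-checked against an independent ROC
package in the tests.

## Problem sizes and known limitations

The shipped analyses use the default cohort — 30 healthy plus 30
diseased subjects, 12 s walks at 20 Hz, roughly 9 usable steps per
foot — for every end-to-end result, with 20 label-permutation
replicates for the chance-level control; these sizes give stable class
effects while keeping every script quick to re-run. Known
limitations: the per-step entropy needs enough active samples for a
meaningful histogram, so very short stances degrade the stepwise
features; the generator's effect sizes are calibrated to reproduce the
qualitative ordering (diseased entropy higher, heels least
informative), not any quantitative clinical effect; and accuracies
obtained on synthetic cohorts say nothing about clinical performance.
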