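---
title: "From raw acceleration to daily affect models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw acceleration to daily affect models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement problem

actiflux implements the measurement-and-analysis chain of an ambulatory
study design in which elementary-school children wear a waist-mounted
triaxial accelerometer (sampling at 30 Hz, recording -6 to +6 g) for
several weeks while rating their momentary affect on twelve 5-point Likert
items, four times a day, on a smartphone. The scientific question at the
end of the chain is a within-person one: do days on which a child is more
physically active than is usual *for that child* differ in affect from that
child's less active days?

Answering it requires five stages, each of which this package implements
and tests: a per-frame feature summary of the raw signal,
reference-pattern activity classification, non-wear cleaning, daily
summaries of activity and affect, and two-level mixed-effects models.
Because no raw data ship with the package, a synthetic-data generator is a
first-class module: it emulates every input the chain consumes, with known
ground truth, so each stage can be validated end to end.

# Frame features

The raw signal is cut into non-overlapping frames of 2.5 s — 75 samples
per axis at 30 Hz. The short frame is deliberate: children's movement is
irregular and comes in short bouts, and a long window would smear brief
runs into their sedentary surroundings. A trailing partial frame is
discarded.

Each frame is summarized by 12 key-values: per-axis mean and variance, the
three pairwise inter-axis correlations, and a per-axis spectral energy.
Numerical conventions, fixed so that models are reproducible:

* **Variance** uses the population (1/n) normalizer.
* **Correlation** of a zero-variance axis is defined as 0. Non-wear frames
  are constant on all axes; the classifier needs a finite value there, and
  0 is the unique value carrying no directional information.
* **Energy** is the sum of squared discrete-Fourier magnitudes excluding
  the zero-frequency (gravity) component, under the length-normalized
  transform: a pure sinusoid of amplitude $a$ has energy $a^2/2$
  regardless of frame length. By Parseval's identity this equals the
  frame's mean squared deviation from its mean, and the test suite checks
  that identity against a brute-force time-domain computation for
  arbitrary signals. The DC term is excluded so that orientation (gravity)
  enters the feature vector only through the means, not through the energy.

# Activity classification

Classification is reference-pattern based: every child moves in an
idiosyncratic way, so a classifier trained on a child's own labelled
reference recording (a fixed protocol of lying, sitting, standing, slow
walking, fast walking and running, plus a device-on-table non-wear
recording) outperforms a generic one. Children who missed the reference
session are classified with a *general* model trained on the pooled
reference data of all children who took part — exactly the concatenation
of their reference sets, with nothing held out.

The classifier is a radial-basis-kernel support vector machine with
one-vs-one multiclass voting (package **e1071**), with `cost = 1` and
kernel width `gamma = 1/12` (one over the number of features), the
defaults commonly recommended for that implementation. All three are
exposed as arguments. Features are standardized to the training set's
mean and SD; a zero-spread feature gets unit scale; the standardization is
frozen into the model and re-applied verbatim at prediction time, so no
information flows from the data being classified back into the scaling.

The package also ships a deliberately simple nearest-centroid classifier.
It is not used in the pipeline; it exists as an independent cross-check in
the tests, because in the zero-noise synthetic regime both classifiers
must reach 100% held-out accuracy, and agreement between two unrelated
decision rules is stronger evidence than either alone.

# Non-wear cleaning

Three steps, in order:

1. **Consolidation.** Runs of classified non-wear of at least an hour are
   treated as true non-wear even if short activity bursts are embedded in
   them (the device being nudged on a table). The rule is formalized
   existentially: an activity epoch is re-classified to non-wear if and
   only if it lies inside *some* interval whose endpoints are non-wear
   epochs, in which each embedded activity burst lasts at most 5 min, all
   embedded activity totals at most 5 min, and the non-wear content is at
   least 60 min. Two readings of the tolerance were possible (per burst,
   or per block in total); the implementation enforces both, the stricter
   combination. Likewise "bordered by an hour of non-wear" is read as an
   aggregate over the block, not an hour on each side. After the merge,
   any remaining non-wear run shorter than 60 min is re-classified to
   sitting: a short motionless stretch is far more plausibly a very steady
   phase of sedentary behaviour than a device taken off and put on again
   within the hour. Every re-classification is flagged, and epoch count
   and timing are never altered. The implementation is run-based with
   bounded forward extension; the tests compare it against a literal
   O(n^2) enumeration of the rule on every coarse label sequence of up to
   12 epochs, and check idempotence and conservation on random days.
2. **Wake-window restriction.** Each morning the child reports bed time of
   the previous night and wake time; a day's usable window is
   `[wake, bed)` — half-open, so an epoch starting exactly at wake counts
   and one starting exactly at bed does not. The bed time of day *d* comes
   from the report of morning *d + 1*; a day missing either report has no
   defensible window and is dropped entirely rather than imputed.
3. **Valid days.** Wear time is 2.5 s times the retained wake-window
   epochs not labelled non-wear; a day is valid with at least 6 h of wear,
   inclusive. Only valid days enter summaries and models.

# Daily summaries

Lying and sitting count as sedentary behaviour, standing as inactive
behaviour, slow and fast walking as moderate-to-vigorous physical activity
(MVPA), running as very vigorous activity. The two model predictors are
`pa_fraction`, active time (MVPA + very vigorous) as a share of worn time,
and `vigorous_share`, the very vigorous share of active time — defined as
0 on a day with no active time (avoiding 0/0 while keeping the day).

Affect: per occasion, each factor's composite is the mean of its three
items, counted only when all three were answered; the day score is the
mean over available occasions, with `n_occasions_used` recorded per
factor so sensitivity analyses can filter on compliance. Days with zero
complete occasions for a factor get a missing score and drop out of that
factor's models listwise.

Descriptives per variable: grand mean and SD over child-days, the average
intra-individual SD (each child's own across-day SD, averaged), and the
intraclass correlation — the between-child share of total variance, so
that one minus the ICC is the within-child share. The ICC is estimated
from the empty two-level model (random-intercept REML), consistent with
the modelling machinery; a one-way method-of-moments estimator is provided
as an independent cross-check and the two agree within 5% on balanced
panels in the tests.

# The two-level models

For child $i$ on day $t$:

$$\text{Affect}_{ti} = \beta_{0i} + \beta_{1i}\,\text{Trend}_{ti}
  + \beta_{2i}\,\text{PA}_i + \beta_{3i}\,\text{PA}_{ti} + \varepsilon_{ti}$$

$$\beta_{0i} = \gamma_{00} + \sigma_{0i}, \quad
  \beta_{1i} = \gamma_{10} + \sigma_{1i}, \quad
  \beta_{2i} = \gamma_{20}, \quad
  \beta_{3i} = \gamma_{30} + \sigma_{3i}$$

with $\text{PA}_i$ the child's mean activity over the study and
$\text{PA}_{ti}$ the day's deviation from it (person-mean centering, so
within-child deviations average exactly zero). The person mean is a
between-person quantity written at level 1; the only estimable reading is
as a child-constant covariate with a fixed coefficient, which is how it is
implemented. The trend is coded as days since the child's first included
day, 0-origin, so the intercept is the expected first-day affect;
calendar gaps advance the trend. The random intercept and random trend
covary; the random daily-activity slope is independent of both.

The model-building sequence is empty, trend-only, all fixed effects, then
the final model adding the random daily-activity slope. Estimates are
REML (via **lme4**, bobyqa optimizer with a tightened stopping
tolerance); because restricted likelihoods are not comparable across
fixed-effect structures, every fit also records its ML deviance (by
refit) for nested comparisons. Wald z tests at the 0.05 level are used for
the fixed effects, without small-sample df correction — the behaviour of
the mixed-model software class this design historically used; users
wanting Satterthwaite can refit with **lmerTest**.

Variance components are constrained non-negative; an estimate at the
boundary is reported as 0 with a missing SE. For interior estimates, SEs
of the variance components come from the curvature of an *exact*
block-wise REML deviance evaluated per child
($V_i = Z_i G Z_i^\top + \sigma^2 I$), implemented independently of lme4
and exposed as `hlm_deviance()`. That function doubles as an oracle: the
tests verify that lme4's optimum reproduces its value to 1e-6 and sits at
a local minimum, and that with all variances forced to zero the fixed
effects collapse to ordinary least squares within 1e-6.

# The synthetic-data generator

The generator is the package's study stand-in, and its defaults are fixed
once:

* **Signal model.** At rest the device reads a gravity unit vector in
  device coordinates plus white noise; locomotion adds a sinusoid
  (vertical axis, half-amplitude in phase on the anterior axis) at 1.6 Hz
  / 0.25 g (slow walk), 2.2 Hz / 0.45 g (fast walk), 3.0 Hz / 0.80 g
  (running); postures differ by orientation (upright, 15-degree reclined
  sit, supine); non-wear is one of three flat resting orientations with
  0.001 g noise. Default wear noise is 0.03 g; the six classes remain
  separable in feature space up to about 0.05 g. This model is the
  package's own construction — real reference sessions record real
  children — and that is precisely what makes perfect-classification
  regimes available for testing.
* **Schedules.** Each day draws a bout sequence inside a wake window of
  7:00 +/- 30 min to 21:00 +/- 30 min (plausible for 3rd/4th graders):
  bout types with probabilities (sitting .33, standing .22, slow walk
  .15, fast walk .10, running .08, non-wear .07, lying .05) and
  exponential durations (means 15, 5, 3.5, 2.5, 3, 30, 15 min), snapped
  to the 2.5 s grid. In expectation this yields roughly 12% of worn time
  active with roughly a quarter of active time running, and 12-13 h of
  daily wear — a compliant child in a cohort whose averages sit near 15%
  active time, ~21% vigorous share and ~11.5 h wear. Every day is flanked
  by 65 min of device-on-table non-wear so the overnight non-wear edge
  exists in every trace.
* **Affect.** Daily factor means follow the two-level model above, with
  per-factor defaults emulating such a cohort: positive dimensions high
  on the 1-5 scale (~4), negative low (~1.5-1.7), substantial intercept
  variance, small negative trends for the positive dimensions, weak
  unreliable daily-activity effects. The intercept-trend correlation is
  set to -0.3 (a value the design does not pin down). Item responses are
  the day mean plus Gaussian item noise (SD 0.4), rounded and clipped to
  1..5 — the simplest mechanism producing Likert data; the induced
  attenuation is acknowledged by also emitting the pre-discretization
  means in the ground-truth tables, and parameter-recovery tests use the
  continuous outcome.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: biomechanical gait realism (harmonics,
inter-stride variability, posture transitions), device artefacts
(calibration drift, clipping during impacts), label noise in real
reference sessions, informatively missing affect occasions, and children
whose compliance collapses. Classifier accuracies near 100% are
properties of the separable synthetic regime, not forecasts of field
accuracy.

# Problem sizes and calibration checks

The package's statistical checks run at sizes chosen to make Monte-Carlo
error small relative to the tolerances while keeping the default test run
short: parameter recovery uses 100 replicates of 100 children x 20 days
(all recovered within 3 Monte-Carlo SEs); the Wald test's size uses 400
null replicates of 50 children x 10 days. Two points deserve note:

* *Which null?* With the random-slope variance generated exactly at 0 the
  fitted slope variance sits at its boundary and inflates the Wald SE of
  $\gamma_{30}$, making the test conservative (empirically ~0.02-0.03).
  Size is therefore calibrated at an interior null (slope variance 0.02),
  where the rate is ~0.05; the boundary null is separately asserted never
  to be anti-conservative.
* *Recovery regime.* With activity spread as tight as a realistic daily
  activity share (SD ~0.08), the slope variance is barely identified at
  this scale and its boundary-truncated estimator is biased upward by
  construction; recovery is therefore checked with activity drawn uniform
  on [0, 1] and slope variance 0.25, a regime that tests the estimator
  rather than the identification limit.

The end-to-end run (raw signal to fitted models) uses 10 children x 10
days in a generated world where daily activity has no effect on any
affect dimension; across seeds, the daily-activity effect is
non-significant in well over 90% of fitted models, the qualitative
pattern such a null world should produce.

# Known limitations

* The consolidation rule's two tolerance readings (per burst vs per
  block) are both enforced; a study wanting the laxer reading must relax
  the rule.
* Wear days are attributed by calendar date; a wake window crossing
  midnight is not split beyond date assignment.
* Wald z inference is anti-conservative for the *between*-person
  coefficient $\gamma_{20}$ when children are few; the within-person
  daily-activity test, the package's focus, is well calibrated at the
  sizes above.
* The SVM's hyperparameters are fixed defaults, not tuned; no
  cross-validation study is included by design.
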