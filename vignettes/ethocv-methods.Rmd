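---
title: "Methods: simulated collar data, probabilistic behaviour classification, and honest cross-validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated collar data, probabilistic behaviour classification, and honest cross-validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ethocv)
```

## The problem this package addresses

Animal-borne inertial loggers produce long streams of tri-axial
acceleration, angular rate and attitude, from which machine-learning
models classify units of behaviour. Two methodological traps are common
in how such models are evaluated:

1. **Random train/test splitting on correlated data.** Behavioural
   datasets typically come from a handful of animals, each contributing
   hundreds or thousands of windows. Randomly splitting windows lets the
   same animal appear on both sides, so the evaluation measures how well
   the model recognizes *already-seen animals*, not how it will perform
   on a new one. Per-individual (leave-one-subject-out) cross-validation
   is the honest estimate for the common use case of deploying a model
   on unlabelled animals.
2. **Optimizing a probability-threshold accuracy.** When accuracy is
   computed by recoding each window against a confidence threshold
   (below-threshold answers count as "rejections"), the metric can be
   maximized by a model that is *never confident and always wrong*:
   every window becomes a true negative and the metric saturates at 1
   while ordinary accuracy is 0. Optimizing hyperparameters against this
   metric therefore favours models that discard data.

`ethocv` packages both phenomena as reproducible experiments: a
synthetic-data generator whose statistical structure makes the traps
appear on demand, the full segmentation → feature → classifier →
evaluation chain, and experiment runners for within/cross-group
accuracy matrices, CV-strategy comparisons, and cross-group transfer
confusion matrices.

## The synthetic signal model

Real collar recordings are not statistically characterized anywhere we
can cite, so the generator is the *simplest* model that makes the eight
ethogram classes (lay, sit, stand, walk, trot, run, eat, drink)
separable yet individually signed. For one behaviour interval the
acceleration in the device frame is

$$a_i(t) = g_i + A_i \sin(2\pi f t + \phi_i) + \varepsilon_i(t),
  \qquad \varepsilon_i \sim N(0, \sigma^2),$$

where $g$ is the behaviour's posture (a unit gravity vector, rotated by
the individual's collar-attitude offset), $f$ its fundamental frequency
and $A$ its per-axis amplitude. Angular-rate channels carry the same
oscillation without the gravity term; attitude channels hold the
slowly-varying Euler angles plus noise. Eat/drink additionally receive
short exponentially decaying bursts (chewing, lapping) at a Poisson-like
rate (`burstiness` events per second).

Defaults (per `default_behaviour_models()`): passive postures differ
mainly in $g$ and are nearly quiescent (amplitudes ≤ 0.03 g, below the
validated 0.05 g quiescence bound); gaits share the upright posture and
differ in frequency — walk 1.5 Hz < trot 2.5 Hz < run 3.5 Hz, an
ordering that is validated, with the specific values configurable — and
amplitude; feeding behaviours are head-down postures with bursts.

**Amplitude–frequency coupling.** Peak acceleration of an oscillating
body scales as $(2\pi f)^2 X$ for displacement amplitude $X$. The
generator therefore multiplies the acceleration amplitude by the squared
ratio of the effective frequency to the group-baseline frequency (and
the angular-rate amplitude by the first power). Without this, a
frequency-shifted run keeps run-level amplitudes and the documented
"classified as slower" transfer error cannot arise, because amplitude
features dominate the classifier.

### Groups and individuals

A `group_profile` is a body-size class: `size_scale` divides all gait
frequencies and multiplies amplitudes (big animals cycle slower and move
their collars further); `run_frequency_shift` adds a group-specific
offset to the run gait only. The default roster is three dog-like size
classes (0.80, 1.00, 1.25) plus a wolf-like group (1.30) whose run is
shifted −0.8 Hz so that it lands near the large-dog trot — reproducing
the asymmetric error pattern in which a transferred model reads the
target's runs as the slower gait. (The source study's text speculates in
the other direction about absolute wolf speed; what its confusion matrix
shows, and what we emulate, is the error direction.)

An `individual_profile` is an animal's signature: log-normal multipliers
on frequency and amplitude and normal collar-attitude offsets, with
log-scale spreads proportional to the **individual effect λ**:
frequency log-sd $0.25\lambda$, amplitude log-sd $0.35\lambda$,
orientation sd $0.60\lambda$ rad. At $\lambda = 0$ the multipliers are
exactly 1 and the offsets exactly 0, making individuals exchangeable.
The package default is $\lambda = 0.6$, calibrated once (before the
acceptance suite was frozen) so that the synthetic world reproduces the
qualitative regime reported for real collar data: leave-one-subject-out
overall accuracy around 0.5–0.6 while random-split accuracy is near 1.
Smaller spreads (our first attempt used 0.10/0.20/0.20) leave the eight
classes separable across individuals and the whole methodological point
disappears.

**What the generator does not emulate:** collar slip and fur-damped
transients, terrain, within-interval gait drift, autocorrelated sensor
noise, label noise at behaviour transitions (the clipping step exists,
but the labels themselves are exact). A green test on synthetic cohorts
establishes that the *pipeline and its statistics* behave as described,
not that any particular accuracy level will be attained on real animals.

### Seeding

All randomness flows from one master seed through `derive_seed()` (a
Lehmer-style mix kept below $2^{31}$), with separate streams for
profiles, signal noise, fold assignment and calibration, so cohorts are
byte-identical on re-run and adding an individual does not perturb the
others.

## Segmentation and features

Each labelled interval is clipped by 1 s at both ends (annotation error
absorption) and cut into 1.3 s windows every 0.5 s; a window whose end
coincides exactly with the clipped end is admitted (the boundary rule is
otherwise unspecified, and this makes a 3.3 s interval yield exactly one
window). The closed form
`floor((L - 2*clip - window)/step) + 1` (with a 1e-9 epsilon guard for
the inclusive boundary) is property-tested against brute-force start
enumeration. Windows are sample-aligned; at 50 Hz a window holds
`round(1.3 * 50) = 65` samples.

The default feature registry maps each window to 54 features: per
channel mean, sd, min, max, RMS (45); pairwise correlations within the
accelerometer and within the gyroscope triads (6, with zero-variance
channels contributing 0); signal magnitude area of acceleration (1); and
the dominant periodogram frequency of the mean-removed acceleration
magnitude with its power (2). The original study's exact feature list
lives in supplementary material that is not available; this is a
standard inertial-classification set, and the registry is pluggable so a
different set can be swapped in without touching other modules. One
subtlety: the magnitude of a *zero-mean* single-axis sinusoid is
full-wave rectified and dominates at $2f$; real signals oscillate around
a gravity baseline, so the magnitude carries $f$ itself. Tests inject
sinusoids riding on such a baseline.

Features are z-scored before classification (the RBF kernel is scale
sensitive). Scaling parameters are fitted on training rows only and
refitted inside every cross-validation fold; the trained model stores
its scaler so prediction cannot leak test statistics.

## The classifier

A soft-margin SVM with RBF kernel
$k(x, z) = \exp(-\gamma \lVert x - z \rVert^2)$, trained one-versus-one
over the $\binom{K}{2}$ class pairs, with class probabilities obtained
by Platt-sigmoid calibration per pair (fitted on decision values from an
internal 3-fold CV whose assignment is seeded) and pairwise coupling of
the pairwise probabilities into a $K$-vector (the standard
quadratic-program construction; fixed-point iteration on its KKT
system). Hard predictions are the row-wise argmax of the probabilities,
with exact ties going to the earlier class in the lexicographically
sorted class list. No SVM implementation is available in the supported
dependency set, so the binary dual is solved by an SMO routine in
compiled code (second-order working-set selection, stopping tolerance
1e-3, joint clipping that lands alphas exactly on their bounds — the
latter matters: naive per-alpha clipping leaves 1e-15 residues that trap
the working-set selection). Development-time validation against a
reference implementation agreed in the dual objective to 5–6
significant figures across extreme hyperparameters, and a frozen
decision-value oracle is part of the test suite.

Argmax is taken over probabilities, not raw decision values; the two can
disagree under pairwise coupling, and both evaluation metrics are
defined on the probabilistic answers.

## Metrics, cross-validation, grid search

**Overall accuracy** is the fraction of windows whose argmax class is
true. **Threshold accuracy** recodes each window against a threshold
$\tau$ using the probability of the *predicted* class: correct ∧
$p \ge \tau$ → TP, correct ∧ $p < \tau$ → FN, incorrect ∧ $p \ge \tau$ →
FP, incorrect ∧ $p < \tau$ → TN, and then
$(TP + TN)/(TP + TN + FP + FN)$. Candidates default to
$\{0.5, 0.6, 0.7, 0.8, 0.9\}$ and the maximizing threshold is chosen
(smallest on ties). Two boundary conventions are ours to fix: equality
$p = \tau$ counts as above, and the "associated probability" of an
incorrect identification is its argmax-class probability (this is what
makes both FP and TN realizable). Useful identities, all tested exactly:
with every confidence above $\tau$ the two metrics coincide; with every
confidence below, threshold accuracy equals one minus overall accuracy;
any $\tau \le 1/K$ forces coincidence because a $K$-class probability
vector's maximum is at least $1/K$. The degeneracy theorem — overall
accuracy 0 with threshold accuracy 1 — is exercised as a constructed
predictor in the tests.

**Cross-validation.** Per-individual folds hold out one whole animal
each. Random folds come in two modes, repeated 70/30 splits and k-fold
(both readings exist in the source description; the comparison runner
defaults to k-fold with k equal to the number of individuals, and the
mode is recorded in every report). Per fold the classifier is refit with
fold-local standardization; the report carries per-fold values, their
mean, and a 95% CI as mean ± 1.96·sd/√n (a t-quantile option exists; the
interval construction was unspecified). When the threshold metric is
optimized, the threshold maximizes the *mean across folds* (the stricter
per-configuration nesting). Confusion matrices accumulate over all
folds' test predictions and are row-normalized, with empty rows flagged;
class merging (e.g. lay/sit/stand → passive, eat/drink → feeding) sums
counts before renormalizing, which can only grow total diagonal mass.
Chance level is reported as $1/K$ = 0.125 alongside the empirical
majority-class baseline, since imbalance makes $1/K$ conservative.

**Grid search** evaluates every (C, γ) of a log-spaced grid — the full
published space is 27 points over $[10^{-5}, 10^9]$ for C by 24 over
$[10^{-9}, 10^3]$ for γ, 648 pairs; the desk-scale default is 7×6 over
the same ranges with the full grid behind `full_grid = TRUE` — choosing
the best mean metric with ties to smallest C then smallest γ, and
persists the full table.

## Experiment runners

`run_group_matrix` optimizes each group by per-individual-CV grid search
under both metrics, reports the cross-validated accuracy on the diagonal
and, off-diagonal, refits the chosen model on the entire source group to
predict every other group (refitting, rather than averaging fold models,
is the conventional reading of using "the optimized model"). All four
metric×optimizer panels are produced. `run_cv_comparison` evaluates both
CV strategies with identical fixed hyperparameters per group, so the
random-minus-individual gap is attributable to the splitting strategy
alone. `run_transfer_confusion` chooses hyperparameters on the combined
source groups only, refits, and reports the target group's raw and
passive/feeding-merged confusion matrices. Leakage guards (no shared
individuals across any train/test boundary, target never in source
optimization) are asserted inside the runners, not just tested.

## Numerical and statistical choices

- SMO: stopping tolerance 1e-3 (1e-5 in the oracle test), iteration cap
  1e6, dense kernel matrices (training pairs here are hundreds of rows).
- Platt calibration: Newton with backtracking on the stabilized
  objective; pairs with fewer than 3 examples of either class fall back
  to training decision values.
- Coupling: fixed-point iteration, tolerance 1e-12, ≤ 100 sweeps;
  probabilities clamped to [1e-7, 1 − 1e-7] before coupling.
- Window boundary inclusive; count formula guarded by 1e-9 against
  floating-point underrun of the inclusive case.
- Permutation null for the chance-level check: labels are permuted
  *within* individuals. A single global permutation of exactly balanced
  labels biases leave-one-subject-out accuracy below chance, because a
  test animal that drew extra windows of one class depletes that class
  from the training side (anti-learning); the within-individual
  permutation is the exchangeability null that matches the resampling
  unit.
- Confidence interval over seeds in the CV-gap experiment: normal
  approximation over ≥ 5 independent cohort seeds.

## Known limitations

- The generator's realism is qualitative by construction; no claim about
  absolute accuracies on real collars follows from it.
- Platt + coupling probabilities are calibrated per pair, not jointly;
  like the reference one-versus-one implementation, coupled
  probabilities can disagree with raw decision values near ties (the
  package takes argmax over probabilities, consistently with both
  metrics).
- The desk-scale grid (7×6) is coarse; conclusions about *which* C, γ is
  best at full HPC resolution should use `full_grid = TRUE` and
  patience.
- Confidence intervals over 4–7 folds are approximate whichever quantile
  is used; they are reported because the experiment design calls for
  them, not because 7 folds estimate a variance well.
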