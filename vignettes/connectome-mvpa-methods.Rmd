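---
title: "Connectome-based MVPA of paired resting-state fMRI: models and methods"
author: "connMVPA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-based MVPA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connMVPA)
```

# The problem

A paired resting-state fMRI design scans each subject twice — before and
after an intervention — and asks whether the pattern of whole-brain
functional connectivity carries enough information to tell the two brain
states apart. connMVPA implements the full multivariate pattern analysis
(MVPA) chain for this question: regional time-series preparation, Fisher-z
Pearson connectivity features, Kendall-tau feature selection, RBF-kernel
support vector classification under leave-one-out cross-validation (LOOCV),
and a whole-pipeline permutation test, with consensus-connection and
region-weight reporting of the edges that drive the discrimination.

The canonical design the defaults mirror is 25 subjects by 2 sessions, 180
acquired volumes at TR = 2 s with the first 5 discarded (175 retained
frames), and a 116-region AAL-style parcellation, whose correlation matrix
yields $116 \times 115 / 2 = 6670$ edge features.

# The feature space

Each session's regional series (frames × regions) is reduced to a Pearson
correlation matrix $R$; the row-major upper triangle
$(1,2), (1,3), \dots, (R-1,R)$ is extracted and Fisher z-transformed,
$z = \operatorname{artanh}(r)$. One fixed edge-indexing convention
(`edgeIndex()` / `pairIndex()`, 1-based region IDs matching atlas labels)
is used in every output; the convention is arbitrary, but a single fixed one
prevents silent edge mislabeling. Correlations with $|r| \ge 1 - 10^{-7}$
(degenerate synthetic cases) are clipped before the transform with a
warning rather than refused.

# Discriminative scoring

For feature $i$ with values $x_{ij}$ over samples $j$ labelled
$y_j \in \{+1, -1\}$ (post/pre), the package scores relevance with a Kendall
tau over unordered sample pairs: a pair $(j,k)$ is concordant when
$\operatorname{sgn}(x_{ij}-x_{ik}) = \operatorname{sgn}(y_j-y_k) \ne 0$,
discordant when the two signs are opposite and non-zero, and neither when
either sign is zero (within-class pairs, exact value ties — the standard
Kendall tie convention, which resolves the ambiguity a literal reading of
the concordance definitions leaves for doubly-tied pairs). The statistic is

$$\tau_i = \frac{n_c - n_d}{n^2}.$$

The $n^2$ denominator is kept as stated in the source method even though
unordered-pair counting bounds $|\tau|$ near $1/4$ for balanced classes:
only the sign of $\tau_i$ (direction of the post-training change) and the
ranking by $|\tau_i|$ (discriminative power) are consumed downstream, and
both are invariant to the denominator. Selection retains the top-$k$
features by $|\tau|$, ties broken by ascending edge index so selection is
deterministic.

# Classification and cross-validation

The classifier is a soft-margin SVM with the Gaussian kernel

$$k(x_i, x_j) = \exp\!\left(-\frac{\lVert x_i - x_j\rVert^2}{2\sigma^2}\right),
\qquad \sigma = 2 \text{ by default},$$

so the exponent at the default width is $-\lVert\Delta\rVert^2/8$. The dual
problem is solved by sequential minimal optimization with
maximal-violating-pair working-set selection, implemented in compiled code
inside the package; its solutions are verified in the test suite against an
independent libsvm solve (decision-value agreement on random problems) and
against the Karush–Kuhn–Tucker conditions directly. Features enter
unscaled (Fisher-z units); a study-level standardisation step is
deliberately absent because the feature space is already
variance-stabilised.

LOOCV holds out one sample per fold; feature ranking and selection are
recomputed on the training fold only, so the held-out sample can never
influence the features or the model that predict it (the suite verifies
this by mutating a held-out sample and checking the fold's selection is
unchanged). Performance is summarised by the generalization rate (GR, the
proportion of held-out samples predicted correctly), sensitivity
(post-training samples correct) and specificity (pre-training samples
correct). `sweepGr()` repeats the full LOOCV over a grid of $k$ (default
40–300 in steps of 20) and $C$ (default 0.005 to 2 in steps of 0.05,
a conventional reading of start:step:end notation) and reports the GR
surface and its maximiser, ties resolved toward the smallest $k$ then the
smallest $C$; the sweep maximum is an optimistic performance estimate and
is reported as such.

## A note on LOOCV at chance and the choice of C

Two finite-sample properties matter when interpreting synthetic
experiments. First, LOOCV on balanced classes is *pessimistically* biased
at chance: the held-out sample's class is always the minority of its
training fold, so a classifier with any imbalance sensitivity scores below
0.5 on null data (we measure ≈ 0.43 at $C = 1$ on small null studies).
Leak-free pipelines can fall below chance but cannot beat it on null data,
and that one-sided property is what the suite asserts. Second, at the very
small penalty $C = 0.01$ every dual coefficient sits at the bound and the
decision reduces to a majority vote over the training fold, which under
LOOCV predicts every held-out sample wrong (GR 0) regardless of signal.
$C = 0.01$ remains the package default operating point (`svmConfig()`), as
it is the sweep optimum reported for the original study's data, but the
package's own synthetic validation experiments use $C = 1$ — the standard
SVM default — so that the classifier is responsive to the planted signal;
this choice was fixed a priori as part of the experimental design, and the
permutation machinery is identical under either value.

# Consensus connections and region weights

Because selection is refit per fold, the selected sets differ slightly
across folds. The *consensus functional connectivity* is their
intersection — the edges selected in every fold. Each consensus edge gets
one sign from $\tau$ computed on the full sample set (+1 increased after
the intervention, −1 decreased); per-fold selections are retained for
audit, since a per-fold sign would not be unique. The *region weight* of
region $r$ is its degree in the consensus graph; weights sum to twice the
consensus size.

# Permutation inference

Significance of the observed $GR_0$ is assessed by rerunning the *entire*
pipeline — per-fold tau ranking, selection, SVM training, LOOCV — on $B$
label-shuffled copies (default $B = 1000$; the validation experiments use
$B = 99$), with the add-one estimator

$$p = \frac{1 + \#\{GR^* \ge GR_0\}}{1 + B},$$

ties counting toward the numerator and $p$ therefore never 0. Shuffles are
drawn uniformly with replacement; a shuffle that would leave a training
fold single-class is redrawn and logged, never silently skipped. Two
schemes are provided: `free` permutes all labels (the default, matching the
method as described), `paired` flips pre/post within subject, available
because the design is paired.

Recomputing selection inside every shuffle is essential. The package
exposes a deliberately broken variant (`selection = "static"`, selections
frozen to those from the unpermuted labels) purely as a negative control:
on null data it inflates the type-I error well above the nominal level
(datasets whose features happen to correlate with the labels elevate
$GR_0$, and frozen-selection nulls never reproduce that elevation), which
is the bias the full recomputation removes. The suite calibrates the valid
variant at $\alpha = 0.05$ over 200 null studies and demonstrates the
inflation of the broken one on the same studies.

# Time-series preparation

The preprocessing module assumes realignment, normalisation and smoothing
are done upstream by standard tools and covers the numerical steps that
feed connectivity directly:

- **Initial discard** — first $k$ frames (default 5) dropped for magnetic
  saturation.
- **Nuisance regression** — OLS residuals against any covariate matrix
  (motion parameters, global mean, white matter, CSF), intercept always
  included; rank-deficient designs are refused naming the collinear
  columns.
- **Band-pass** — Chebyshev Type I (order 4, 0.5 dB ripple, both
  configurable), passband 0.01–0.08 Hz, applied forward-backward
  (`signal::filtfilt`) for zero phase. The source method names the filter
  family and band but not the order/ripple; tests assert passband and
  stopband behaviour rather than coefficients.
- **Scrubbing** — frame-wise displacement
  $FD_i = \sum |\Delta \text{trans}| + r \sum |\Delta \theta|$ with
  rotations converted to arc length on a sphere of radius $r = 50$ mm
  (degrees converted to radians first); $FD_1 \equiv 0$. This
  sum-of-absolute-differences form is the convention of the scrubbing
  literature the method builds on — the only form consistent with summing
  three translational and three rotational displacements into one mm
  value. Frames with $FD > 0.5$ mm are replaced by per-region linear
  interpolation between the nearest unflagged neighbours; flagged runs at
  the series boundary take the nearest unflagged value, since one-sided
  linear interpolation is undefined. Scrubbing is idempotent. Motion files
  must declare their rotation unit (radians by default, the
  realignment-tool convention); an undeclared unit is an error rather
  than a guess.
- **Parcellation** — per-frame voxel means within each integer atlas
  label, regions ordered by ascending label ID.

The default order is discard → regression → band-pass → scrub. The source
description does not pin an order (and reports no material difference with
and without scrubbing); the order is therefore a configuration knob whose
default is recorded in every run log.

# The synthetic-data generator

No data were deposited with the original study, so the generator is the
package's ground truth. `generatePairedStudy()` draws each session as a
zero-mean multivariate Gaussian whose correlation matrix is a common base
(off-diagonal `base_corr`, default 0.1 — a weak positive background typical
of z-scored regional BOLD) plus, post-session only, the planted per-edge
shifts (`PlantedEffect`; default shift 0.3, a value chosen once as a
moderate, detectable connectivity change — the original study reports no
effect sizes). Subject heterogeneity is a per-subject jitter of the base
correlations (SD 0.02), shared between a subject's two sessions so that
pre/post differences carry only the planted effect plus sampling noise.
Each target matrix is repaired to positive definiteness by clipping
eigenvalues below $10^{-6}$ and rescaling to unit diagonal, preserving the
planted structure approximately; a planted target outside $(-1, 1)$ is an
error naming the offending edge. Series are white by default with an
optional AR(1) coefficient; temporal filtering effects are tested
separately in the preprocessing module. Everything is bit-reproducible
under a seed.

`generateMotionTrace()` produces a Gaussian random-walk on the six
rigid-body parameters with optional single-frame spikes (which is why a
spike at frame 1, where FD is undefined, is refused), and
`generateFeatureDataset()` is a feature-level shortcut (Gaussian features,
informative subset mean-shifted between classes, balanced paired labels)
for classifier and permutation experiments that do not need the
connectivity stages.

What the generator does *not* emulate: spatial voxel structure (only a
block-label volume is constructed in tests for the parcellation
round-trip), haemodynamic autocorrelation beyond AR(1), physiological
nuisance structure, and site/scanner effects. Passing tests therefore
demonstrate the correctness and calibration of the *algorithms* under a
known generative model, not the reproducibility of any particular
real-data result.

# Validation problem sizes

The package's own experiments (test suite and acceptance script) use:
planted-effect recovery at the full design scale (25 subject pairs, 116
regions, 175 frames, 20 planted edges at +0.3, selection size $k = 20$
matched to the planted-set size, permutation $B = 19$ per replicate, 20
replicates); permutation calibration on 200 null feature-level studies of
10 pairs × 50 features at $B = 99$; and the negative control on the same
200 null studies. These sizes were chosen to give stable Monte-Carlo
verdicts (99% binomial confidence bands) at desk-scale runtimes.

# Known limitations

- The hyperparameter sweep reports its maximum without nested
  cross-validation, so the reported GR at the sweep optimum is optimistic;
  this mirrors the source procedure and is flagged in the output rather
  than corrected.
- Consensus edges carry no edgewise inferential statement (no per-edge
  p-values); the permutation test covers the classifier, not individual
  connections.
- Partial correlation, regularised covariance and windowed (dynamic)
  connectivity are out of scope.
- With strong regularisation (very small $C$) the LOOCV majority artifact
  described above makes GR uninformative; the permutation test remains
  valid but powerless there.

# Session info

```{r}
sessionInfo()
```
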