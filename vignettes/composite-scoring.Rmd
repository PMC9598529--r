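---
title: "Composite scoring of an outcome battery: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite scoring of an outcome battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(composcore)
```

`composcore` turns an eight-measure clinical outcome battery, collected
under a two-condition crossover design, into a single health composite per
(subject, condition) record, and tests the condition effect on that
composite. This vignette is the package's own account of the method: what
is modelled, which knobs matter, what the synthetic data generator does and
does not emulate, and where the design was genuinely open.

## The scoring model

Records are standardized per measure (`z = (x - mean)/sd`, sample SD with
the n−1 denominator) and fed to a width-1-bottleneck autoencoder

\[ z = h_1(w_1 x + b_1), \qquad x' = h_2(w_2 z + b_2), \]

concretely: input(8) → dense(hidden, activation) → dropout → dense(1,
linear) → dropout → dense(hidden, activation) → dense(8, linear). The
bottleneck activation is linear so the composite lives on an unbounded
interval scale; encoder and decoder share the hidden width and activation.
Training minimizes the mean squared reconstruction error averaged over all
entries, with the Adam optimizer in full batch. The composite score of a
record is the activation of the central neuron at inference, with dropout
disabled.

The baseline is correlation-matrix PCA: eigendecomposition of the sample
covariance of the standardized battery. The PC1 score plays the same role
as the bottleneck activation. A width-1 *linear* autoencoder trained to
convergence attains exactly the top principal subspace, which gives a sharp
cross-check: with linear activations and no dropout, the training-set
explained variance must match the PC1 variance fraction (the test suite
asserts agreement within 0.02 on a 200×8 matrix, and that the autoencoder
never exceeds PC1 beyond numerical tolerance). The autoencoder can only
improve on PCA through nonlinearity.

Model quality is summarized by the explained variance
\[ \mathrm{EV} = 1 - \frac{\operatorname{mean}_k s_k^2}{\operatorname{mean}_k \widehat{\operatorname{var}}_k(x)},
\qquad s_k^2 = \frac{1}{n-1}\sum_i (x_{ik} - x'_{ik})^2 , \]
together with the raw mean residual variance. The ratio form is required to
report EV as a percentage of variance captured; on self-standardized data
the denominator is 1. EV ≤ 1 always, equality iff reconstruction is
perfect, and it may be negative when a reconstruction is worse than the
column means — which genuinely happens on 2-record test sets (see
*Evaluation protocol*).

## Tunable parameters

| Parameter | Default | Units / range | Why this default |
|---|---|---|---|
| `hidden` | 24 | neurons | battery-sized bottleneck architecture; searched over {10, 12, 16, 24, 32} |
| `activation` | relu | — | searched over {relu, tanh, sigmoid, linear} |
| `dropout` | 0.4 | rate in [0, 1) | heavy regularization for very small n |
| `learning_rate` | 0.01 | Adam step | standard for this scale of problem |
| `epochs` | 2000 | full-batch steps | tiny datasets converge well within this budget |
| `patience` / `min_delta` | 200 / 1e-5 | epochs / loss | plateau early-stop; saves time without changing the optimum materially |
| `rho` | 0.8 | share of SD in [0, 1) | strong shared health factor, matching the premise that the measures co-move |
| `tau` | 0.8 | correlation in [0, 1] | high within-subject stability expected in a crossover |
| `delta` | 0 | latent SD units | the marginal calibration already carries the condition effect; nonzero values would double-count |
| `gamma` | 0 (0.5 in the nonlinear preset) | quadratic weight ≥ 0 | at 0.5 the quadratic carries 1/3 of each measure's variance — large enough that a linear rank-1 method visibly underfits |

Epochs, batching and stopping are deliberate choices rather than
quantities with an external referent: with at most a few hundred records,
full-batch gradients remove batch-order nondeterminism, and 2000 Adam
steps at rate 0.01 reach the loss plateau in every configuration the test
suite exercises.

## What the generator emulates — and what it does not

`generate_cohort()` draws, for subject *i* and condition *j*,

\[ h_{ij} = \sqrt{\tau}\, a_i + \sqrt{1-\tau}\, u_{ij} + \delta\, 1[j = \text{better}], \]
\[ z_{ijk} = \rho\, d_k\, h_{ij} + \gamma\, c_k\,(h_{ij}^2 - 1) + \sqrt{1-\rho^2}\, e_{ijk}, \]

with \(a_i, u_{ij}, e_{ijk}\) independent standard normal, \(d\) the ±1
direction-of-improvement vector and \(c\) a balanced ±1 pattern orthogonal
to \(d\) (\(c_k = (-1)^{k+1} d_k\)). Each column of \(z\) is divided by its
exact population SD \(\sqrt{1 + 2\gamma^2 c_k^2}\) and then mapped
affinely onto the configured per-condition means and SDs. Dividing by the
closed-form SD keeps the marginal calibration and the correlation
structure orthogonal knobs: the published marginals are matched for any
`rho`/`gamma`.

The quadratic term is a centered function of the *same* latent health
factor, loading on a direction orthogonal to the linear loading. That
placement is what makes it a nonlinearity probe: the records then lie near
a one-dimensional *curved* manifold, so a width-1 nonlinear decoder can
reconstruct the \(c\)-direction variation from the single latent while a
one-component linear projection cannot reach it at all. (A quadratic of an
*independent* second factor, or one loading on \(d\) itself, would instead
be either unlearnable by any width-1 encoder or fully captured by PC1 —
in both cases the linear and nonlinear methods would tie, and the
construction would probe nothing.)

The generator emulates: the published per-measure, per-condition means and
SDs; the direction of improvement of each measure; cross-measure
correlation through a shared health factor; within-subject correlation
across conditions; and an optional nonlinear component. It does **not**
emulate: measurement floors/ceilings (BERG is a 0–56 scale, MFES 0–10 —
generated values are unbounded normals and can exceed the instruments'
ranges), skewness of timed measures, dropout/withdrawal, learning or
fatigue effects across assessment order, or any particular joint
correlation beyond the single-factor-plus-quadratic structure. Passing
tests therefore show that the *pipeline* behaves as specified on data with
the assumed structure — not that real batteries satisfy that structure.

`generate_two_factor()` plants an exact eigenvalue spectrum: solving
\(v_1' + r/8 = v_1\), \(v_2' + r/8 = v_2\), \(v_1' + v_2' + r = 1\) and
drawing \(x = \sqrt{v_1'} u_1 f_1 + \sqrt{v_2'} u_2 f_2 + \sqrt{r/8}\, e\)
gives a population covariance whose top-two eigenvalue shares equal the
targets exactly (the noise variance must be spread as \(r/8\) per
coordinate for the shares to come out right; the tests assert this by
exact eigendecomposition of the constructed covariance, independent of
sampling).

## Evaluation protocol

Out-of-sample quality uses two runs with a 90/10 split: a seeded
permutation of the records is drawn once and the first
\(2\lceil 0.1 n\rceil\) positions are cut into two consecutive,
*disjoint* test sets — the minimal-assumption reading of "two runs with
completely different test sets". Within each run the scaler is fitted on
the training records only (standardization is affine-invariant, so
pre-scaled input does not leak); a `scaler_policy = "all"` switch
reproduces the non-leakage-safe alternative. Splits are at the record
level by default — a subject's two conditions may straddle train and test —
with `split_by = "subject"` available since either reading is defensible
for a crossover.

At 18 records a test set holds 2 records, and an EV computed from 2 rows
is extremely volatile (its denominator is a 1-df variance); negative test
EVs at that size are expected sampling behavior, not training failures.
The test suite therefore checks out-of-sample EV properties at simulated
sizes of 100+ subjects, and uses the training-set EV where a sharp
numerical statement is needed (the linear-AE/PCA equivalence).

Grid search evaluates all activation × width combinations under the same
seed and returns the configuration with the highest mean test EV; exact
ties go to the first configuration in (activation-list, width-list) order,
making the search deterministic.

## Statistical reduction

With one within-subject factor at two levels, the repeated-measures ANOVA
is algebraically the paired t-test: \(F = t^2\), df = (1, n−1), identical
p. The package computes the closed-form t on the paired differences
(second condition level minus the first) and asserts the equivalence
against `t.test()` and `aov(y ~ condition + Error(subject))` in the test
suite — an exact, oracle-checkable implementation rather than a linear
mixed model whose extra machinery adds nothing at two levels. Per-measure
condition tests are the same paired reduction applied to each raw measure
at a 0.05 threshold, with **no multiple-testing correction** across the
eight tests; the summary column is labelled accordingly.

Sign alignment computes the proxy \(p_i = \operatorname{mean}_k d_k
z_{ik}\) and flips the composite iff its correlation with the proxy is
negative. Zero-variance composites make alignment undefined and raise an
error rather than defaulting. Alignment is idempotent; aligned composites
always report both the raw and the aligned value, since a published raw
bottleneck score can legitimately point "down" while the aligned score
points "up".

## Numerical choices and degenerate inputs

* Weights and biases initialize uniformly in \(\pm 1/\sqrt{\text{fan-in}}\)
  from the run seed; dropout masks draw from the same seeded stream, so a
  (data, architecture, seed) triple reproduces training bit-for-bit.
* The per-epoch loss trace and all reported losses are computed
  dropout-free; early stopping watches that trace (patience 200, min-delta
  1e-5). Non-finite training loss raises a divergence error suggesting a
  lower learning rate.
* Sample SDs use n−1 throughout; a zero-variance measure in a scaling
  subset, a single-record subset, fewer than 2 records for any variance,
  fewer than 2 complete pairs, zero-variance paired differences, and
  incomplete subject pairs each raise a specific, named error.
* PCA eigenvalues are clamped at 0 before forming variance fractions
  (guarding tiny negative eigenvalues from finite precision); a relative
  top-eigenvalue gap below 1e-6 is reported as a degeneracy flag by
  `stability_check()` instead of being silently resolved by the
  decomposition's arbitrary basis choice.
* Scoring data are matched to the training battery by column name when
  names are available, by position otherwise; mismatches raise battery
  errors.

## Problem sizes used by the test and acceptance suites

Moment recovery is checked at 10,000 subjects; the planted spectrum at
100,000 records (sample) plus an exact population eigendecomposition; the
linear-AE/PCA equivalence on a fixed 200×8 matrix; the nonlinear
advantage on 100-subject cohorts over 10 seeds (median comparison); the
small-cohort significance property on 9-subject cohorts over 100 seeds;
and the paired-t equivalence on 1000 random fixtures. These sizes were
chosen so each check is decisively powered at desk scale.

## Known limitations

* Only two-condition (paired) designs; no missing data, no imputation, no
  more than two timepoints.
* The architecture is fixed to the seven-layer, bottleneck-of-one shape;
  depth is not parameterized.
* The generator's factor model is an explicit assumption. The published
  loadings constrain but do not determine the measures' joint correlation
  structure, so simulated loadings match the published *sign pattern*, not
  the printed values.
* Real-data headline quantities (the published explained variance and
  composite group means) depend on the unreleased per-subject records and
  are not reproduction targets; the package reproduces the *properties*
  of the analysis on calibrated synthetic cohorts instead.
* At 9 subjects the condition effect implied by the published marginal
  moments alone, with realistic within-subject correlation, yields paired
  tests in the p ≈ 0.01–0.05 range for any unsupervised composite; the
  much smaller p-value reported on the real data additionally reflects the
  actual cohort's per-subject consistency, which summary marginals cannot
  encode.
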