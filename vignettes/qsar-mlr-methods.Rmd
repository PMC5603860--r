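---
title: "Methods: MLR QSAR modelling, validation and domain-aware screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MLR QSAR modelling, validation and domain-aware screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsarscreen)
```

# The model

qsarscreen fits ordinary-least-squares multiple linear regressions of an
activity (pIC50, the negative log10 of IC50) on a small subset of
molecular descriptors:

$$\hat y = b_0 + \sum_{j=1}^{k} b_j x_j .$$

The statistical assumptions are the classical ones — a linear
response in the chosen descriptors, roughly homoscedastic Gaussian
noise, and $n > k + 1$ training compounds with a full-rank design.  The
package's job is everything around that fit that makes a QSAR
defensible: choosing the $k$ descriptors out of hundreds of candidates,
splitting compounds representatively, validating internally and
externally, ruling out chance correlation, and refusing to extrapolate
outside the model's leverage domain.

Internal statistics follow the standard definitions:
$R^2 = 1 - SS_{res}/SS_{tot}$, adjusted
$R^2_{adj} = 1-(1-R^2)(n-1)/(n-k-1)$,
$F = (SS_{reg}/k)/(SS_{res}/(n-k-1))$, and
$SE = \sqrt{SS_{res}/(n-k-1)}$.  Leave-one-out cross-validation uses
the exact algebraic identity for OLS,
$y_i - \hat y_{(-i),i} = e_i/(1-h_{ii})$ with $h_{ii}$ the hat-matrix
diagonal, so PRESS, $Q^2 = 1 - \mathrm{PRESS}/SS_{tot}$ and
$RMS_{cv} = \sqrt{\mathrm{PRESS}/n}$ cost one fit, not $n$.  The test
suite verifies the shortcut against literal refits to $10^{-10}$, and
checks the conservation law $\sum_i h_{ii} = k+1$ on every model.  The
$Q^2$ denominator uses the full-training-set mean: the leave-one-out
variant changes third decimals at these sample sizes and the full-mean
convention is the common one.

# Descriptors

Three families are computed natively; everything else (quantum-chemical
descriptors, logP, surface area, …) enters as precomputed columns
because it requires external engines.

**RDF codes** (3D): $g(r) = f\sum_{i<j} A_i A_j e^{-B(r-r_{ij})^2}$
over unordered atom pairs, $r_{ij}$ the Euclidean distance in Å.
Defaults $f = 1$ and $B = 100\,\text{Å}^{-2}$ — the conventional sharp
smoothing for discrete codes — are configurable, since descriptor
packages do not agree on them and published values for specific
compounds are not exactly recoverable without knowing both.  Names
follow the `RDF###w` convention: the number divided by 10 is the radius
in Å, the letter the weighting.  Weights are carbon-scaled atomic
properties (mass, van der Waals volume, Sanderson electronegativity,
polarizability, or 1 for unweighted); the shipped tables are the
commonly published ones and can be overridden by passing a numeric
vector per atom.

**MATS / GATS autocorrelations** (2D): over the molecular graph with
topological (bond-count) distances $d_{ij}$ and atomic weights $w$,

$$\mathrm{MATS}_k =
  \frac{\tfrac1\Delta \sum_{d_{ij}=k}(w_i-\bar w)(w_j-\bar w)}
       {\tfrac1N \sum_i (w_i-\bar w)^2},
\qquad
\mathrm{GATS}_k =
  \frac{\tfrac1{2\Delta}\sum_{d_{ij}=k}(w_i-w_j)^2}
       {\tfrac1{N-1}\sum_i (w_i-\bar w)^2},$$

where sums run over *ordered* pairs and $\Delta$ counts them.  The
ordered-pair convention is symmetric and is also used by the
brute-force oracle in the tests, so the two routes are comparable to
$10^{-12}$.  Degenerate cases — no pair at the lag, zero weight
variance — return exactly 0 rather than erroring, keeping batch
computation total; this matters when a descriptor table is built over
molecules of varying size.

**C-005** counts methyl carbons bonded to exactly one heavy atom from
{O, N, S, P, Se, F, Cl, Br, I}.  Hydrogens may be explicit; when a
molecule carries none at all, implicit counts are inferred from
standard valences minus the bond-order sum (SDF files routinely omit
hydrogens).

RDF invariance under rigid motion and atom permutation is asserted
numerically to $10^{-10}$ in the tests — these are the defining
properties of a 3D structure code.

# Data preparation

**Constant / near-constant removal** drops zero-variance columns and
columns whose modal value occupies ≥ 95 % of rows (default;
`near_constant_fraction = 1` keeps near-constants).  The 0.95 default
is a choice: "near-constant" has no canonical number, and 0.95 removes
columns that cannot support a stable coefficient at $n \approx 40$.

**Collinearity filtering** examines every pair with $|r| > 0.9$ and
drops the member with the lower absolute correlation to the activity.
Pairs are processed greedily by descending $|r|$, skipping pairs
already resolved — the keep-rule is standard but the processing order
is not; descending severity is reproducible and removes the worst
redundancy first.  The result is verified by exhaustive scan to contain
no surviving pair above the threshold.

**Kennard–Stone splitting** autoscales descriptors (zero mean, unit
variance), seeds the training set with the most distant pair, then
repeatedly adds the candidate maximising the minimum distance to the
selected set.  Autoscaling is a deliberate choice: unscaled Euclidean
distance would let large-magnitude descriptors dominate the selection.
Distance ties are broken by comparing standardized coordinate vectors
lexicographically, then by original row index, which makes the selected
*set* invariant to row order (asserted under shuffling).  The algorithm
runs in post-filtering descriptor space.

# Subset selection

**Stepwise** regression alternates forward entry (smallest partial-F
p-value, if below 0.05) and backward removal (largest p-value, if above
0.10) until neither applies.  The partial F for a single variable is
the square of its $t$ statistic, referred to $F(1, n-k-2)$.  These
F-probability defaults are the conventional entry/removal criteria.

**The genetic algorithm** encodes a descriptor subset as a bitstring
and minimises the LOO $RMS_{cv}$ of the encoded model.  Configuration
and rationale:

* population 100; tournament selection of size 2 and uniform crossover
  (the selection scheme and crossover type are open choices; both are
  the simplest standard operators, and tournament-2 needs no fitness
  scaling for an error-valued fitness);
* crossover probability ramps linearly 90 % → 60 % and per-bit mutation
  0 % → 1 % across generations.  The endpoints come as ranges without a
  stated direction, so a direction had to be fixed: increasing mutation
  combats late-stage premature convergence while decreasing crossover
  stabilises good building blocks.  Both endpoints are arguments, so
  the opposite reading is expressible;
* elitism of one chromosome; chromosomes encoding 0 descriptors, more
  than `max_descriptors`, or a rank-deficient design get infinite
  fitness.  `max_descriptors` defaults to $\lfloor n/4 \rfloor$ — at
  $n = 35$ that is 8, about the largest subset a 35-compound training
  set can support without memorising it;
* evolution stops when 90 % of the population shares the best fitness
  (to $10^{-12}$) or at the generation cap.  The stop rule is stated in
  the source material as "90 % of the generations", which is not well
  defined; population-share is the standard reading;
* all randomness flows from a single integer seed, and repeated
  fitness evaluations are cached by chromosome, so runs are
  deterministic and fast.

**When selection is well-posed.**  Subset selection over hundreds of
*mutually independent* candidates with $n = 35$ falls to Freedman's
paradox: the best of ~280 chance correlates beats a true descriptor
in-sample at each step, stepwise saturates ($R^2 \to 1$, external
predictivity $\to 0$), and the GA's feasible-subset landscape becomes
deceptive.  This is a property of the statistics, not of the
implementation — real descriptor pools are heavily inter-correlated
and shrink drastically under the collinearity filter, which is why the
classical workflow is viable on real data.  The package therefore
demonstrates and tests selection on pools of ~40 candidates (where
recovery of a planted model is provable) and documents that users
should prune aggressively before selecting.  Stepwise and the GA are
composable — `stepwise_select()` output can serve as the GA's candidate
pool — and the acceptance pipeline uses the GA with its subset-size
guard for the final model.

# Validation

**External set statistics.**  For observed $y$ and predicted
$\hat y$ on compounds never used in training: $r^2$ is the squared
Pearson correlation; through-origin slopes
$k = \sum y\hat y/\sum\hat y^2$ and $k' = \sum y\hat y/\sum y^2$;
through-origin determination coefficients
$R_0^2 = 1-\sum(y-k\hat y)^2/\sum(y-\bar y)^2$ and
$R_0'^2 = 1-\sum(\hat y-k'y)^2/\sum(\hat y-\bar{\hat y})^2$.  Several
through-origin conventions circulate; these are pinned and unit-tested
against an independently computed 5-point fixture.  The decision rules:
$Q^2 > 0.5$; $r^2 > 0.6$; $|(r^2-R_0^2)/r^2| < 0.1$ for either
$R_0^2$ variant; $0.85 \le k \le 1.15$ for either slope — the third and
fourth rules are disjunctions, as conventionally applied.

**rm².**  The published formula $r^2(1-\sqrt{r^2-R_0^2})$ takes a
square root that is negative whenever $R_0^2 > r^2$ — which happens for
perfectly ordinary predictions (including the reference workflow's own
numbers).  The widely used absolute-difference variant
$r^2(1-\sqrt{|r^2-R_0^2|})$ is therefore computed, with threshold
$rm^2 > 0.5$; both the $R_0^2$- and $R_0'^2$-based values are reported,
the former as primary.  Differences below $10^{-12}$ under the root are
snapped to zero, because the square root would amplify $10^{-16}$
rounding into an $10^{-8}$ bias and break the identity
$rm^2 = r^2$ when $R_0^2 = r^2$.

**Y-randomization** shuffles the activity vector under a seeded
permutation and rebuilds a model per repetition, recording $R^2$ and
$Q^2$.  The default mode reruns the same selection procedure that
produced the original model (a "new model is developed" per shuffle);
`refit_fixed` refits the fixed descriptor set and is used where
hundreds of repetitions are needed cheaply.  The testable guarantee at
$n = 35$, $k = 8$ on pure noise is that the 95th percentile of shuffled
$R^2$ stays below 0.6 and the mean shuffled $Q^2$ is negative — the
suite asserts exactly that with 200 permutations.

**Applicability domain.**  Leverage
$h_i = x_i(X^TX)^{-1}x_i^T$ (intercept-augmented) against the stored
training design; warning threshold $h^* = 3(k+1)/n$ — for a
35-compound, 8-descriptor model, $h^* = 27/35 = 0.77$.  Membership is
strict ($h < h^*$): a compound exactly on the threshold is treated as
outside, matching the "lower than the threshold" reading.  Training
compounds additionally carry the $|r_i| > 2.5$ standardized-residual
outlier flag (strict inequality), giving the Williams-plot coordinates.
For numerically exact fits ($SE$ below $10^{-10}$ of the activity
spread) standardized residuals are defined as zero rather than $0/0$.

# Screening

`screen_candidates()` predicts every candidate, attaches leverage and
the in-domain flag, and sorts by descending prediction with ties broken
by candidate ID.  Nothing is silently dropped — out-of-domain
candidates are flagged, and filtering is an explicit opt-in — because a
screening report that hides its extrapolations invites exactly the
misuse the applicability domain exists to prevent.

# The synthetic generator

`simulate_qsar_data()` emulates the *shape* of a small-molecule QSAR
matrix: $n = 46$ compounds by $p = 300$ descriptors by default, with an
8-descriptor linear signal, Gaussian activity noise
($\sigma = 0.3$ pIC50 units), five collinear pairs at $r = 0.95$, and
three constant columns.  The sizes mirror a 46-compound study modelled
with 8 descriptors after a 35/11 Kennard–Stone split; the planted
coefficients (0.5–0.9 in absolute value, mixed signs, intercept 6) are
fixed once as realistic pIC50-scale effects giving a clearly
identifiable but noisy signal, and are not tuned per test.

Design choices: descriptor columns are standard normal (no canonical
marginal distribution exists for a generic descriptor; scale/shift
arguments support robustness tests).  The collinear partner is built as
$x' = r\,\tilde x + \sqrt{1-r^2}\,\tilde z$ where $\tilde x$ is the
standardized base column and $\tilde z$ is noise *empirically
decorrelated* from it — this controls the sample correlation exactly,
not just in expectation, so the planted structure is guaranteed at any
$n$.  One integer seed drives the whole stream, and the generator
saves/restores the global RNG state so it has no side effects.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: real descriptor marginals
(counts, bounded ratios, heavy tails), the block-correlation structure
of descriptor families (our fillers are independent, which makes
selection *harder* than on real pools of equal size, see Freedman's
paradox above), activity-dependent noise, and measurement error in the
descriptors themselves.

# Problem sizes and runtime

The test suite and the acceptance pipeline run at the study's natural
scale: $n \le 50$ compounds, selection pools of ~40 descriptors,
GA population 100 for at most 200 generations, 200 Y-randomization
permutations, 20-fixture oracle sweeps.  At these sizes the full suite
completes in well under a minute; fitness caching makes the GA's cost
proportional to the number of *distinct* chromosomes evaluated.

# Known limitations

* Descriptor values are not bit-compatible with proprietary descriptor
  software: $B$, $f$, radius grids and atomic-property scalings vary
  between implementations and are not published alongside model
  equations.  Models built on qsarscreen descriptors are
  self-consistent but not interchangeable with models built elsewhere.
* MLR only — no PLS, ridge/lasso or nonlinear learners; the method's
  scope is the classical interpretable-equation workflow.
* The leverage domain is the only applicability criterion; distance-to-
  model and density variants are out of scope.
* Stepwise carries no subset-size guard (its classical definition has
  none); on wide pools of independent candidates it will overfit by
  construction.  Use the GA (which has the $n/4$ guard) or prune first.
* No conformer generation: 3D descriptors use SDF coordinates as-is.
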