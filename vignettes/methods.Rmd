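---
title: "Methods: PLS-VIP analysis of pessary fitting from dMRI measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PLS-VIP analysis of pessary fitting from dMRI measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pessaryfit)
```

## The problem and the data model

Whether a vaginal pessary fits — stays in place without movement, rotation
or expulsion — is a binary clinical outcome that current practice predicts
poorly. The hypothesis behind this pipeline is that pelvic-floor anatomy,
quantified on dynamic MRI, carries that signal. Each participant
contributes a fixed grid of measurements: eight anatomical parameters
(lengths in cm, the levator hiatal area in cm², angles in degrees), each
assessed at rest, during pelvic-floor contraction and during Valsalva, and
— for six of the eight — under four pessary conditions (none, ring, ring
with support, Falk). Sacrococcygeal straight length and the
pubococcygeal–sacral angle are measured only without a pessary, so the
grid holds 6 × 3 × 4 + 2 × 3 = 78 variables. The grid is deliberately
flat: the coronal-plane provenance of the hiatal area is metadata, not
structure, and the canonical ordering (parameter, then manoeuvre, then
pessary) fixes column order and all ranking tie-breaks.

Such cohorts are small (the motivating design has 9 fitting and 6
non-fitting participants) and the variables are strongly collinear — the
same anatomy measured under twelve conditions. Partial least squares is
the natural regression family here: it tolerates p ≫ n and collinearity by
building a few orthogonal score directions that maximize covariance with
the response.

## Preprocessing

Variables are z-scored to mean 0 and sample SD 1 (denominator n − 1, the
convention of standard statistical toolboxes; any constant factor between
the n and n − 1 conventions is absorbed by the PLS scaling). Statistics
are computed over *observed* entries only: the pipeline normalizes before
imputing, so missing cells must not contaminate the column statistics.
Missing cells are then set to 1 × 10⁻⁶ — essentially the column mean after
centring — so that an unmeasured value neither pulls the fit nor creates a
spurious signal. The outcome is coded +1 (fitting) / −1 (non-fitting).

A column that is constant within the data at hand cannot be scaled; it is
mapped to all zeros with a warning rather than raising an error, because
resampling folds of a 15-participant cohort can easily render a column
constant and a single such column must not abort an exhaustive
cross-validation.

## PLS1, explained variance, VIP

The regression core is NIPALS PLS1. With centred `X` and `y`, component
`a` uses the weight `w_a ∝ X_a' y_a` (unit norm), score `t_a = X_a w_a`,
X-loading `p_a = X_a' t_a / t_a't_a` and y-loading
`q_a = y_a' t_a / t_a't_a`, deflating both matrices each round. For a
univariate response this is deterministic — there is no random
initialisation — and at `A = min(n − 1, p)` on complete full-rank data the
regression vector equals ordinary least squares, which the test suite
verifies against `lm()` and against an independent PLS implementation
(mixOmics). If a deflation round finds no remaining covariance with the
response, the decomposition is truncated at the last usable component.

Explained-variance fractions per component are computed from the deflation
residuals (`t_a't_a · p_a'p_a / ||X||²` for X, `q_a² t_a't_a / ||y||²` for
y). The number of components for the initial variable-importance analysis
is not something a 15-participant dataset can settle by itself, so the
default is operational: the smallest A whose cumulative explained response
variance reaches 0.9, capped at `min(n − 1, p)`, and configurable
everywhere a component count is accepted.

Variable importance in projection uses Wold's formula,
`VIP_j = sqrt(p · Σ_a SSY_a w_ja² / Σ_a SSY_a)` with
`SSY_a = q_a² t_a't_a`. The identity mean(VIP²) = 1 is exact and is
asserted to 10⁻⁸ across random fits. Ranking ties are broken by canonical
grid order so reports are reproducible.

## Variable selection and exhaustive cross-validation

The study design is two-stage: an initial PLS on all variables produces
the VIP ranking, then the top k = 1…10 variables feed a second
("validation") PLS whose held-out performance is measured by exhaustive
leave-one-out (n folds) and leave-two-out (all n(n−1)/2 pairs; each
participant predicted once per possible co-held-out partner, n(n−1)
predictions in total) cross-validation. A held-out continuous prediction ŷ
is called fitting if ŷ > 0.1, non-fitting if ŷ < −0.1, and unknown in the
closed middle zone — boundary values land on "unknown" because the middle
zone exists precisely to absorb ambiguity. Counts satisfy
correct + incorrect + unknown = total by construction, and the
leave-two-out calls (+1/−1/0) fill a participant × co-held-out-participant
matrix with an empty diagonal.

Two methodological knobs are deliberately exposed rather than decided:

* **Selection mode.** The default (`"pooled"`) selects the top-k variables
  once, on the full cohort, and then cross-validates only the model fit —
  mirroring the two-stage design the pipeline reproduces. This incurs
  selection bias: the held-out participant influenced which variables were
  chosen. The `"nested"` mode re-ranks variables inside every training
  fold, paying the bias back with a different variable set per fold.
* **Normalization mode.** The default (`"global"`) z-scores and imputes
  the full matrix once, before folding, matching the stated order of
  operations of the design; `"fold"` recomputes normalization statistics
  within each training fold and applies them to the held-out rows.

Neither alternative is asserted to be what the original analysis did; the
defaults reproduce the described procedure, the alternatives quantify its
optimism.

A training fold can be degenerate: leaving two participants out of a
cohort with a 3/2 class split can strand a single class, and a constant
submatrix leaves no usable component. The default policy
(`degenerate_fold = "unknown"`) treats such folds' predictions as
undecidable — they are recorded with an `NA` continuous response and an
"unknown" call, keeping every count identity intact; a strict `"error"`
policy is available. This choice follows from the decision rule's own
logic: the unknown category is where the pipeline puts what it cannot
decide.

## The synthetic cohort generator

`generate_cohort()` exists so that every downstream stage has a testable
ground truth. It emulates the features of the real data that the analysis
actually leans on:

* two outcome groups of configurable size (default 9 fitting / 6
  non-fitting, the motivating design);
* within-participant correlation among the 3–12 conditions of the same
  parameter, modelled as an exchangeable block
  (`sqrt(ρ) · shared + sqrt(1 − ρ) · noise`, default ρ = 0.5) — this
  matches the physical source of the collinearity (one anatomy measured
  repeatedly) and is positive definite by construction for any ρ ∈ [0, 1);
  distinct parameters are generated independently;
* designated informative variables with a configurable standardized mean
  difference between groups. The default informative set is the six
  variables the motivating analysis ranked highest (TVL at
  Valsalva/no pessary, TVL at rest/no pessary, CL at rest/ring-support,
  sacrococcygeal angle at Valsalva/ring-support, TVL at rest/ring,
  pubococcygeal angle at rest/ring), at a default effect of 1.5 SD — a
  strong but plausible separation for an exploratory imaging biomarker;
* missing-completely-at-random cells (default rate 0.02, mimicking
  occasionally unreadable images; no missingness mechanism is known for
  the real data, so nothing more structured is attempted);
* base means and SDs on the measurement scale (e.g. TVL 7.3 ± 1.2 cm at
  rest on dMRI, hiatal area 17 ± 4 cm², sacrococcygeal angle
  110 ± 12°) — documented guesses, since the true inter-variable
  magnitudes are unpublished; only effect/SD ratios matter after
  z-scoring;
* baseline characteristics (age ~ N(69.7, 8.5) years, group BMI means
  27.8/23.9 kg/m², POP-Q stage-3 probability higher in the non-fitting
  group) that feed the baseline statistics only, never the PLS.

What the generator does **not** emulate: real angle distributions are
generated on a linear scale with no wrap-around (all plausible values are
far from 0°/360°); missingness is never informative; correlation across
*different* parameters is absent; and there is no biomechanics — a passing
test shows the pipeline recovers structure of this kind, not that the
anatomy–fitting relationship in any real cohort looks like this.

Generation is a pure function of (sizes, profile, seed), and the global
RNG stream of the caller is saved and restored around it.

## Baseline statistics

The group-comparison layer reproduces a clinical "Table 1":

* pooled mean/SD reconstructs the whole-population summary from per-group
  (n, mean, SD) via total sum of squares (within + between, denominator
  N − 1). Note that pooling two copies of the same group returns the
  group mean but a slightly smaller SD than the group's own — the
  reconstruction targets the SD of the concatenated raw data, which is
  the well-defined convention;
* the independent-samples t-test defaults to pooled variance (Welch is an
  option) and accepts raw values or published summaries; a p-value
  recomputed from rounded summaries bounds, rather than pins, the
  raw-data value;
* the Mann–Whitney U test is exact up to combined n = 20 by full
  enumeration of rank assignments with midranks for ties (two-sided via
  the symmetric rule P(|U − n₁n₂/2| ≥ |U_obs − n₁n₂/2|)), with a
  tie-corrected normal approximation above;
* the exact contingency test uses the hypergeometric distribution for
  2 × 2 tables and full enumeration of margin-fixed tables (multivariate
  hypergeometric probabilities) for r × c, needed for the three-level
  avulsion row. The two-sided p-value sums the probabilities of all
  tables no more probable than the observed one — the point-probability
  rule; conventions that instead double a one-sided tail give different
  numbers, which is why the choice is fixed and documented. Degenerate
  margins (an empty row or column) return p = 1.

## Problem sizes and tolerances

Algebraic identities (VIP normalization, PLS-equals-OLS at full rank,
score orthogonality) are asserted at tolerances 10⁻⁶–10⁻⁸ over dozens of
random instances of size n = 10–12, p = 4–7. Cross-validation identities
run at n ∈ {5, 10, 15}. Recovery experiments use 20 seeds at n = 100/100
(all six informative variables expected in the VIP top 10) and 20
null-effect seeds at n = 9/6, where leave-one-out accuracy on a fixed
six-variable set is expected to hover around chance; the fixed set — no
data-driven selection — is used there so that the measured accuracy
reflects the generator's null, not selection optimism. These sizes keep
the full suite under a minute on one CPU while leaving the Monte-Carlo
bands comfortably wide.

## Known limitations

The pipeline evaluates the *procedure*, not any clinical claim: with 15
participants, pooled-mode cross-validation accuracy is an optimistic
estimate (see selection mode above), the unknown-zone half-width 0.1 is a
convention inherited from the motivating design rather than a calibrated
quantity, and VIP rankings from a single small cohort are unstable —
which is exactly why the synthetic generator and the nested/fold-wise
modes exist. Angles near the 0°/360° seam, informative missingness and
cross-parameter correlation are outside the generator's scope.
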