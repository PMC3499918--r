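---
title: "Why reciprocal reading-speed scores disagree: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Why reciprocal reading-speed scores disagree: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recipz)
```

## The problem

A single reading performance — so many syllables in so many seconds —
yields two scores: seconds per syllable (`time_per_unit`) and syllables per
second (`units_per_time`). They are mutual reciprocals, hence carry the
same information, and normative batteries provide norms on either scale as
if the choice were cosmetic. It is not. Diagnostic practice standardizes
the score against a normative mean and SD and flags |z| ≥ 2 in the
pathology direction; the reciprocal is a *nonlinear* (hyperbolic) map, so
equal z-distances on one scale are unequal on the other. `recipz` makes the
size of the resulting disagreements computable.

The whole analysis is governed by one parameter: the **Mean/SD ratio**
r = μ/σ of the normative sample. If X ~ Normal(μ, σ) is the sec/syll norm,
a patient at sec/syll z-score z has raw score μ(1 + z/r), and the same
performance scores

$$z_y(z; r) = \frac{1/\big(\mu(1+z/r)\big) - \mathrm{E}[1/X]}{\mathrm{SD}[1/X]}$$

on the reciprocal scale. Both numerator and denominator scale as 1/μ, so
$z_y$ depends on (μ, σ) only through r — `map_z()` therefore takes the
ratio as its distribution argument, and the suite checks the invariance
under (μ, σ) → (cμ, cσ) explicitly. Real normative samples have r around
5–10, which is exactly the regime where disagreements are large.

## The estimand: positivity-conditioned reciprocal moments

E[1/X] does not exist for a normal X — the density is positive in any
neighbourhood of 0. The simulation resolves this the way any finite
simulation implicitly does: draws at or below a small bound ε are
redrawn. The default generator bound is ε₀ = μ/1000, with a
`reject_run` policy for anyone who wants a run to fail rather than be
conditioned (`sim_config(positivity_policy=)`). The redraw count is
recorded on every sample; at r = 3 about `n·Φ(−3) ≈ 0.00135·n` draws are
affected, at r ≥ 5 essentially none.

The quadrature oracle (`conditional_reciprocal_moments()`) computes
E[1/X | ε < X < μ + 10σ] and its SD by adaptive integration of the
renormalized density (relative tolerance 1e−10; the mass beyond 10σ is far
below that). Its lower bound deserves care, and this is the one place the
package makes a genuinely non-obvious design choice. The conditional
*second* moment is dominated, at small r, by the extreme left tail: at
r = 5, integrating down to μ/1000 gives SD[1/X] ≈ 0.263, yet the region
below μ − 4σ that drives this value is visited by a 20,000-draw sample
with probability well under one half. A Monte Carlo run of the study size
can therefore never agree with the μ/1000-conditioned moment, not because
either is wrong but because they answer different questions. The oracle's
default lower bound is accordingly the **sample-resolution quantile**: the
1/(2n) tail quantile of the ε₀-conditioned normal (n = 20,000 by default,
`quadrature_spec(resolution_n=)`). Below it lies mass a study-size sample
has less than an even chance of ever touching. With this estimand the
quadrature at (μ = 1, σ = 0.2) gives mean 1.0461 and SD 0.2453 — verified
against a 2·10⁷-draw Monte Carlo during development — and "oracle equals
MC within 3 replicate SEs" is a well-posed check, which the acceptance
suite runs at r ∈ {4, 5, 6, 10, 50}. Users can set
`quadrature_spec(epsilon=)` to any explicit bound and observe the tail
sensitivity directly; the test suite does, asserting that the μ/1000 bound
inflates the conditional SD above 0.26.

The delta-method series (`series_reciprocal_moments()`) is the second,
closed-form cross-check: E[1/X] ≈ (1/μ)(1 + v + 3v² + 15v³ + 105v⁴) and
E[1/X²] ≈ (1/μ²)(1 + 3v + 15v² + 105v³ + 945v⁴) with v = (σ/μ)². The
series is asymptotic, not convergent — its terms grow beyond order 4, so
higher orders are deliberately not offered; it agrees with quadrature to
0.5% in the mean at r ≥ 6 and drifts up to ~10% in the SD at r = 5.

## Monte Carlo machinery

Every stochastic estimate uses `sim_config()`: N = 20,000 draws per
replicate (the study's normative sample size) and 10 replicate seeds, so
each reported value carries a replicate standard error instead of the
unreported single-run noise it would otherwise hide. Child seeds are
derived from the root seed by deterministic modular mixing keyed on
(ratio, replicate), so any single table cell can be recomputed in
isolation and `map_z(z, r, config)` equals the corresponding
`build_mapping_table()` cell exactly. A single-run mode
(`replicates = 1`) mimics a one-shot simulation.

The mapping-table grids default to ratios {3, 4, 5, 6, 8, 10, 15, 20, 30,
50} and z ∈ {0.5, …, 4}: the ratio range spans what normative reading
samples actually show, and the z grid covers the diagnostic band through
gross impairment. Ratio 3 rows are printed but intrinsically unstable
(the reciprocal sample routinely contains values in the hundreds); the
generator warns below ratio 3.

`crossing_point()` solves $z_y(z; r) = -2$ for z — the upper end of the
**discrepancy region**, inside which a performance is pathological on
sec/syll and normal on syll/sec. The reciprocal-scale moments are
estimated once, frozen, and the root found by monotone bracketing and
bisection to 1e−6 in z; re-simulating inside the solver would make the
bracketing incoherent. Per-replicate roots supply the SE. Two numerical
facts matter here. First, the root is ~2r/(m − 2s)² times as sensitive to
the reciprocal SD s as to anything else — about 32× at r = 5 — so its
Monte Carlo noise is an order of magnitude above a table cell's. Second,
the sampling distribution of a 20,000-draw reciprocal SD is right-skewed
(a single draw near the bound inflates it), so the replicate-averaged root
at r = 5 centres near 4.07–4.15 across root seeds, about 0.1–0.2 z-units
above what a single clean run reports; both are within the estimator's own
noise of each other. At the ±2 cut-off the region's finite-ratio upper end
exceeds the cut-off by roughly 3/r, approaching it only in the linear
limit r → ∞ (2.065 at r = 50).

## What stays invariant

Monotone decreasing transforms reverse order and nothing else:

* **Percentiles** under the midrank convention 100(rank − 0.5)/n with
  average ranks on ties satisfy p_X(x) + p_Y(1/x) = 100 *exactly*, ties
  included — the midrank convention is fixed precisely so this identity is
  algebraic rather than approximate.
* **Rank-sum tests** on raw scores and reciprocals give complementary U
  statistics (U_y = n_a·n_b − U_x) and identical two-sided p-values.

What does not survive is anything interval-based: by strict convexity,
for y₁ < y₂ ≤ y₃ < y₄ with y₂ − y₁ = y₄ − y₃ one always has
1/y₁ − 1/y₂ > 1/y₃ − 1/y₄, so equal gains on one scale are never equal on
the other unless the pairs coincide. `demo_interaction_flip()` turns that
into the applied worst case: a two-group pre/post design with *identical*
syll/sec z-gains of 1.0 at baselines z = −4 versus z = −1 (syll/sec norms
Normal(2.0, 0.4), i.e. ratio 5; subject noise SD 0.08 in raw syll/sec
units; 12 subjects per group). The interaction is tested by permuting
group labels over subject gains — chosen over a parametric mixed ANOVA
because the claim under test is about orderings and the permutation test
imports no distributional assumptions; the same label permutations are
applied to both scales so the two p-values differ only through the scale.
The shipped configuration (seed 20121116, 2,000 permutations by default)
yields p ≈ 0.0005 on sec/syll and p ≈ 0.22 on syll/sec: a significance
flip at α = 0.05 from data in which the generating-scale effect is null by
construction. The effect sizes and noise level are the package's own
choice of a realistic, reproducible demonstration — nothing in the
underlying analysis pins them down — and a zero-noise config is rejected,
since all permuted statistics would tie and the p-value would be
undefined.

## Degenerate inputs, tie-breaks, conventions

* A z exactly at the cut-off counts as pathological ("at least 2 SDs"
  read inclusively). No borderline band is encoded; the z is always
  reported so callers can impose their own.
* `delta_z()` is signed so that positive = clinical improvement on either
  scale (improvement is a falling score on time-per-unit, a rising one on
  units-per-time).
* Patient placements at or below zero (z ≤ −r) are rejected: they lie at
  or beyond the hyperbola's pole, where no reciprocal score exists.
* Every score carries an explicit scale tag and cross-scale mixing is an
  error, never a silent coercion — silent mixing is the mistake under
  study.
* Classifications, moments, tables and flip reports serialize to JSON/CSV
  with a run manifest (command, config echo, seeds, package version) so
  any stochastic output can be regenerated bit-for-bit.

## What the synthetic data does and does not emulate

The generator draws normative scores from a normal distribution on one
scale, which is the standard idealization for normative modelling and the
regime in which the z-mapping table is defined. Real sec/syll samples are
themselves right-skewed, age-structured, and floor-limited; none of that
is modelled, and no age-band norm tables from published batteries are
shipped or fitted. Passing tests therefore establish the internal
consistency and the size of the reciprocal-scale discordance under the
normal model — they do not certify any particular battery's norms. The
pre/post generator likewise adds Gaussian subject noise independently at
the two timepoints; correlated pre/post errors would change power but not
the convexity argument that drives the flip.

## Problem sizes

Unit tests run reduced configurations (n = 5,000, 4 replicates, or
smaller) where only determinism or algebra is at stake; every acceptance
check runs the full study conditions, N = 20,000 with 10 replicates, and
the permutation demonstrator is additionally exercised at 10,000
permutations. The quadrature oracle's reference values are frozen in the
tests to what the 2·10⁷-draw cross-check confirmed.
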