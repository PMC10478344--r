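---
title: "Circumplex structural summary analysis: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circumplex structural summary analysis: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipcssm)
```

## The model

The interpersonal circumplex (IPC) arranges eight octant scales at equal
45-degree intervals around two axes: communion (warmth, x) and agency
(dominance, y). `ipcssm` places PA at 90°, BC at 135°, continuing
counterclockwise to LM at 360° and NO at 45°. When an external construct has
coherent interpersonal content, its correlations \(r_k\) with the eight
octant scores trace a cosine curve over the octant angles \(\theta_k\):

\[ r_k = e + a\,\cos(\theta_k - \Theta) + \varepsilon_k . \]

The structural summary method (SSM) summarizes the profile by four
parameters. Because the angles are equally spaced, the least-squares fit has
a closed form: elevation \(e\) is the profile mean; the vector components
are \(x = \tfrac{2}{8}\sum_k r_k\cos\theta_k\) (communion) and
\(y = \tfrac{2}{8}\sum_k r_k\sin\theta_k\) (agency); amplitude
\(a = \sqrt{x^2+y^2}\); angular displacement \(\Theta = \mathrm{atan2}(y,x)\);
and prototypicality \(R^2 = 1 - SS_{res}/SS_{tot}\), the share of profile
variance around its mean explained by the cosine. `ssm_fit()` implements
exactly this, and the test suite checks it against an independent `lm()`
least-squares oracle and a brute-force grid search.

Two conventions are worth stating because the literature leaves them
implicit. First, \(R^2\) is computed around the profile mean (it equals the
explained variance of the cosine model at equally spaced angles). Second,
for a perfectly flat profile amplitude is zero and both \(\Theta\) and
\(R^2\) are undefined; `ssm_fit()` reports them as `NA` with a warning
rather than forcing 0 or 1, since either choice would silently distort
downstream gating. \(\Theta\) could equivalently be defined as the peak of
the fitted curve; for this closed-form fit the peak and the vector angle
coincide.

## Interpretation gating

Parameters are gated before interpretation (`apply_cutoffs()`):

* elevation and amplitude are interpreted at magnitude \(\ge .10\) (the more
  liberal of the published heuristics, appropriate for normative samples
  with restricted range);
* a profile is prototypical when \(R^2 \ge .70\) (acceptable fit; .80 is
  good). Non-prototypical ("complex") profiles have no unified interpersonal
  theme, so amplitude and angle are not interpreted at all — the
  `differentiated` flag is reported as `NA`, not `FALSE`;
* two angles are treated as meaningfully distinct only when at least 22.5°
  (half an octant) apart, a guard against over-interpreting tiny but
  statistically significant differences in large samples.

## Bootstrap inference

`bootstrap_ssm()` resamples participants (rows) with replacement, refits the
profile per resample, and forms percentile intervals (default B = 2000,
95%). Percentile rather than BCa intervals are used: the published workflow
this package follows reports 95% bootstrapped CIs without further
specification, and percentile intervals are the convention in the circumplex
literature.

Angles live on a circle, so naive percentiles fail near the 0°/360° wrap
(intervals such as [347.2°, 13.6°] are genuine outputs of this analysis).
Each bootstrap angle is therefore recentered on the point estimate into
(−180°, 180°], percentiles are taken on the recentered deviations, and the
point estimate is added back. The resulting arc always contains the point
estimate and is shorter than 360°. Coverage of all five parameters is
verified by simulation in the test suite: with a true profile
(e = .2, a = .3, Θ = 180°) at n = 856, 500 replications at B = 500 must land
in [92%, 98%] for a nominal 95% interval. Those problem sizes keep the
simulation inside a few minutes on one CPU while leaving the binomial
uncertainty of the coverage estimate (±2%) inside the band.

`contrast_profiles()` applies the same machinery to parameter *differences*
of two scales refit on the **same** resampled rows (a paired design —
within-sample dependence is preserved, between-sample contrasts are out of
scope). Angular differences are signed into (−180°, 180°]. Gating is applied
to the point estimates first; a pair in which either member fails the
prototypicality or amplitude cut-off has its angular contrast computed but
suppressed (`angle_status = "excluded"`), recording both facts rather than
choosing between "never computed" and "computed then hidden". Both the point
difference and the bootstrap mean difference are reported: published
difference tables do not always equal the difference of published points,
and keeping both makes the discrepancy inspectable instead of hidden.
Degenerate resamples (a zero-variance column) are dropped and counted in
`B_effective`, never imputed; a run losing more than 10% of its resamples
warns.

## The order-relations randomization test

Circumplex structure itself is checked before profiling. For eight equally
spaced variables, the 28 off-diagonal cells of the octant correlation matrix
fall into four circular-distance classes (45°, 90°, 135°, 180°, holding 8,
8, 8 and 4 cells). Every pair of cells from different classes yields an
order prediction — the closer class should correlate higher — giving 288
predictions. The correspondence index is (met − violated) / 288; ties (equal
within 1e−10) stay in the denominator but add nothing to the numerator.
The tie tolerance is configurable because printed correspondence indices in
the literature cannot disambiguate the convention.

The p-value is the proportion of variable-order relabelings whose index is
at least the observed one. Since the index is invariant under rotations and
reflections of the circular order, only the \(8!/(2\cdot 8) = 2520\)
distinct circular orders need enumeration; counting all \(8!\) permutations
gives the identical proportion. A matrix whose correlations strictly
decrease over distance classes is uniquely optimal among circular orders, so
its exhaustive p is \(1/2520 = .0004\) — the package reproduces this
printed structural constant exactly, and the smallest achievable p is
\(1/2520\) by construction. Sampled mode (for larger k or quick checks)
includes the observed order as one relabeling.

## Scoring, screening, and reliability

Instruments are scored from item-level responses via scoring keys. The
bundled keys are *synthetic*: item counts, response formats and aggregation
match the published instruments (32-item problems circumplex scored 0–4 with
4 items per octant; 64-item sensitivities circumplex scored 1–8 with 8 per
octant; 77 true/false schizotypy items; etc.), but items are assigned to
scales in consecutive blocks — the copyrighted keys are not reproduced.
True/false items are coded 0/1, consistent with published subscale ranges
that equal endorsed-item counts.

Scale scores prorate residual missingness: a score is computed when at least
80% of the scale's items are answered (sum scales return mean of answered ×
item count), else the score is missing. The threshold is a package choice —
retained protocols can have up to 2% blanks, and published workflows rarely
state scale-level handling. Profiles then use pairwise-complete Pearson
correlations.

Protocol screening excludes participants with strictly more than 2% blank
items, infrequency validity scores more than 2.5 normative SDs above the
normative mean, or a manual flag — attributed in that fixed order so ledger
counts are disjoint and deterministic. Normative mean/SD are arguments, not
constants, because they belong to the validity instrument's reference
sample.

McDonald's \(\omega_t\) is computed from a single-factor maximum-likelihood
fit to the item correlation matrix (`stats::factanal`), with a small
minimum-residual fallback on non-convergence, as
\((\sum\lambda)^2 / ((\sum\lambda)^2 + \sum\psi)\). Working on the
correlation matrix makes the coefficient invariant to item rescaling.
Polychoric-based and multi-factor omegas are deliberately out of scope; the
estimator behind published omegas of this kind is typically unstated, and
the ML-on-Pearson choice is verified in tests against the closed form for
parallel items.

## The synthetic-data generator

`synthetic_spec()` describes a population in which each surface's octants
have the circulant correlation \(c_0 + c_1\cos(\theta_j-\theta_k)\) and each
external scale has a prescribed \((e, a, \Theta)\) profile. The population
is realized as a common-factor model — a general factor (weight
\(\sqrt{c_0}\)) plus a circular factor pair (weight \(\sqrt{c_1}\)) per
surface — so the joint correlation matrix is positive semidefinite by
construction, target profiles are hit *exactly* in the population, and
infeasible requests (\(e^2/c_0 + a^2/c_1 > 1\), summed over surfaces) fail
loudly. User-supplied scale-scale overrides go through eigenvalue-clipping
repair with a hard 0.01 distortion cap per entry; silent distortion would
invalidate every recovery test built on the generator.

Defaults are fixed values a circumplex researcher would call realistic: \(c_0 = c_1 = 0.3\) (adjacent octants
r ≈ .51, orthogonal ≈ .30, opposite ≈ 0, the classic inverse-distance
pattern of published octant intercorrelation matrices), n = 856 for study
emulation, and item loadings of .85 when item-level responses are generated.
Items are discretized to each instrument's Likert range via
equal-probability normal thresholds (a skew option concentrates mass in low
categories to mimic the floor effects typical of pathology scales).
Surfaces' latent factors are independent across surfaces; cross-surface
octant correlations are therefore zero, which real problems/sensitivities
data would not show — a deliberate simplification that keeps multi-surface
specs feasible.

What the generator does *not* emulate: non-normal latents (no copulas),
reverse-keyed items, systematic (non-MCAR) missingness, and demographic
covariates. Passing recovery and coverage tests on this generator therefore
demonstrates the *method's* correctness under clean conditions, not
robustness to the messiness of real survey data.

The packaged study fixture (`make_study_fixture()`) draws 929 protocols and
engineers the exclusions deterministically: 31 protocols get 3–10 blank
items (>2% of the 104 items), 39 get careless junk responses with
infrequency sums of 12–20 (far above the synthetic normative threshold of
mean 4 + 2.5 × SD 2 = 9), and 3 are manually flagged — leaving 856. Retained
protocols blank at most 2 items, and only circumplex items, so their
infrequency sums stay exact. Target profiles for the ten external scales are
the published-archetype values (cold ≈ 184°, socially avoidant ≈ 245°,
vindictive ≈ 147°, and so on, on both surfaces). Item-scored octants
attenuate amplitudes slightly relative to the latent targets (4 coarse
Likert items per problems octant cap the octant–latent correlation near
.93; the 8-item sensitivities octants reach .96+), which the fixture checks
accept by design.

## Numerical details worth knowing

* Angles are degrees throughout, counterclockwise, reported in [0, 360);
  signed differences in (−180, 180].
* Quantiles are type-7 (R's default); identical seeds give byte-identical
  intervals, and the pipeline derives every stage's seed deterministically
  from the master seed.
* Correlations are undefined for constant inputs; `correlation_profile()`
  raises an error naming the offending column rather than returning zero.
* `omega_total()` flips the loading vector's sign so its sum is positive;
  with no reverse-keyed items all loadings are then nonnegative.
* The pipeline's CSV output rounds the way published SSM tables print
  (parameters 2 dp, angles 1 dp, \(R^2\) 3 dp); `report.json` keeps full
  precision.

## Known limitations

Mean-based (individual-respondent) SSM profiles, robust or weighted
correlations, BCa intervals, unequally spaced theoretical angles in the
order-relations test, IRT scoring, and cross-sample contrasts are all out of
scope. The bundled instrument keys are schematic and must be replaced with
real keys (via `scoring_key()` or YAML) before scoring real data.
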