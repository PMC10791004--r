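---
title: "Measuring inequality in survey-based coverage indicators: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring inequality in survey-based coverage indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equicov)
```

`equicov` implements health-inequality monitoring for one binary,
favorable coverage indicator (the motivating case is third-dose DPT
immunization among children aged 12–23 months) observed in a two-stage
cluster household survey. This vignette is the package's own account of
the statistical machinery: what each stage assumes, which knobs matter,
how degenerate inputs are handled, and what the synthetic-data tests do
and do not establish about real survey data.

## 1. Subgroup estimation

The indicator is disaggregated by five equity stratifiers: household
wealth quintile and maternal education (ordered from most disadvantaged
to most advantaged), place of residence and child sex (binary), and
subnational region (non-ordered). For subgroup $g$ the point estimate is
the weighted prevalence in percent,
$y_g = 100\sum_i w_i y_i / \sum_i w_i$, and the population share
$s_g$ is the subgroup's share of total survey weight.

**Variance.** The design-based variance uses Taylor linearization of the
ratio estimator under the with-replacement PSU approximation, stratified
by region: cluster totals of $w_i(y_i - \hat p)$ are contrasted within
each stratum with the $m_h/(m_h-1)$ factor. A stratum with a single PSU
contributes no variance (certainty approximation). The 95% interval is
Wald on the logit scale and back-transformed, which keeps it inside
$[0, 100]$; a subgroup at exactly 0% or 100% instead gets a one-sided
exact (Clopper–Pearson-style) bound evaluated at the Kish effective size
$n_\text{eff} = (\sum w)^2/\sum w^2$, because the logit is undefined
there. Subgroups with $n_\text{eff} < 25$ are flagged (`low_n`), never
suppressed: small-cell suppression is a reporting policy, not an
estimation question.

Exact identities hold by construction and are tested:
$\mu = \sum_g s_g y_g$ for every dimension-year, and shares sum to one.

## 2. The six summary measures

* **D** $= y_\text{high} - y_\text{low}$ and **R**
  $= y_\text{high}/y_\text{low}$. "High/low" means: the extremes of the
  stated ordering for ordered dimensions; a fixed convention for binary
  ones (female − male for sex, urban − rural for residence, chosen so
  the signs of published tables are reproduced); best minus worst
  performing for regions. Significance: the CI excludes 0 (D) or 1 (R).
* **SII / RII.** Each ordered subgroup is placed at its ridit — the
  midpoint of its cumulative population-share interval — and a weighted
  least-squares line of $y_g$ on the ridit (weights $s_g$) is evaluated
  at ranks 1 and 0: $\mathrm{SII} = v_1 - v_0$ (percentage points),
  $\mathrm{RII} = v_1/v_0$ (unitless). The regression is on the linear
  (percentage) scale by default; `scale = "logit"` fits log-odds and
  back-transforms the endpoints, which guarantees $v_0, v_1 \in (0,100)$
  at the price of a less interpretable slope. Both indices are
  *inapplicable* (NA) for binary and non-ordered dimensions — a
  two-point regression adds nothing over D/R, and ranks are undefined
  without an ordering.
* **PAR** $= y_\text{ref} - \mu$, floored at 0 when the reference sits at
  or below the national average (for a favorable indicator the
  attributable improvement cannot be negative); the raw value is kept in
  `value_raw`. Reference rules per dimension: richest quintile, highest
  education, urban, female, best-performing region. **PAF**
  $= 100\,\mathrm{PAR}/\mu$, always computed from unrounded internals, so
  $\mathrm{PAF}/\mathrm{PAR} = 100/\mu$ is an exact identity in the
  output.

**Confidence intervals.** When only an estimate table is available
(published tables carry no microdata), subgroup SEs are back-derived
from the reported interval half-widths, and measure CIs follow by the
delta method (log-scale for R and RII, full covariance of $(v_0, v_1)$
for SII/RII since both are linear maps of the same $y_g$). When
child-level records are available, all measure CIs instead come from a
stratified cluster bootstrap: PSUs are resampled with replacement within
region strata and the entire estimate → measure pipeline is recomputed
(default $B = 1000$; tests and the pipeline default use smaller $B$
since percentile endpoints stabilize quickly for these smooth
statistics). Bootstrap replicates that lose a required subgroup are
dropped from the percentile computation.

**Degenerate cells.** $R$ is inapplicable when $y_\text{low} = 0$. RII is
inapplicable when the fitted line crosses zero at rank 0 ($v_0 \le 0$),
which genuinely occurs on the bundled published data for education in
the first survey round: 79.6% of the population sits in the no-education
group at 16.3% coverage, dragging the linear extrapolation below zero.
The package reports NA with a diagnostic rather than silently switching
scales.

## 3. Concentration and Lorenz analysis

The concentration index is $C = 2\,\mathrm{cov}_w(y_i, R_i)/\mu$ with
weighted fractional ranks $R_i = (\text{cum. weight before } i +
w_i/2)/\sum w$ in ascending order of the socioeconomic ranking variable;
tied ranking values share their block's mean rank, making the index
invariant to the input order of ties. The weighted covariance uses the
$\sum w$ normalization (no $n/(n-1)$ correction by default; available
via `small_sample_correction`). The concentration curve accumulates
weighted population share against weighted outcome share in ranking
order; twice the trapezoid area between the curve and the diagonal
equals the covariance form up to $O(1/n)$, and the package attaches the
area-based value to the curve so the two routes can be compared. The
Gini index applies the same construction with units ranked by their own
value. The preferred ranking variable is the continuous latent asset
score when present (synthetic data keeps it; DHS-style quintile input
falls back to quintile ranks with mean-rank ties).

## 4. Trend assessment

Two years differ significantly on a measure when their 95% CIs are
strictly disjoint; touching endpoints count as overlap (the conservative
reading of a non-overlap rule). Because it is not stated whether such
rules apply to adjacent rounds or the full span, verdicts are emitted
for all consecutive pairs *and* the endpoint pair. No multiplicity
adjustment is applied across the many comparisons — matching common
practice in inequality monitoring — and this is recorded in the output's
`multiplicity_adjustment` attribute. The CI-overlap rule is conservative
relative to a two-sample test: disjoint 95% CIs imply a significant
difference, not conversely.

## 5. Two-level determinants model

`fit_multilevel()` fits
$\mathrm{logit}\,P(y_{ic}=1) = \mathbf{x}_{ic}'\beta + b_c$,
$b_c \sim N(0, \sigma^2)$ over communities $c$ — operationalized as the
sampling cluster (PSU), the only community unit a DHS-type design
identifies. Estimation is Laplace (`lme4::glmer`, bobyqa, `nAGQ = 1`);
raising `nAGQ` gives adaptive Gauss–Hermite quadrature, which the test
suite checks against an independent non-adaptive 201-node quadrature of
the marginal likelihood (agreement to $10^{-4}$ on a small fixture).
Odds ratios carry Wald 95% CIs; the ICC is
$\sigma^2/(\sigma^2 + \pi^2/3)$ on the latent scale. The fit is
unweighted by default — survey weights in multilevel models require
scaling choices with no consensus — with a `weights=` passthrough for a
weighted pseudo-likelihood. Degenerate designs fail loudly: constant
columns and aliased (rank-deficient) designs are rejected naming the
term, suspiciously extreme coefficients trigger a separation warning,
and non-convergence is reported, never swallowed.

Maternal age enters linearly (its effect is conventionally reported per
year). Reference levels are configurable per term; switching a reference
inverts the corresponding OR, which is tested.

A practical note on cost: the Laplace fit optimizes jointly over the
variance parameter and all fixed effects, so a pooled multi-round model
with many categorical terms (survey year × region × five quintiles × …)
can take minutes on a single core; `nAGQ = 0` (penalized quasi-likelihood
style PIRLS) is one to two orders of magnitude faster and, on generated
data of this structure, gives nearly identical fixed effects and only a
mildly attenuated variance — acceptable for exploration, not for final
ICC reporting.

## 6. The synthetic survey generator

The generator exists so that every downstream stage can be exercised and
validated without restricted microdata. It emulates:

* **Design:** region strata; PSUs drawn with probability proportional to
  simulated enumeration-area size from a frame six times the take;
  a fixed take of 28–30 households per PSU (default 29); 0/1/2
  age-eligible children per household with probabilities (0.55, 0.40,
  0.05), keeping one-child households dominant as in a 12-month age
  band; weights = inverse product of the two stage-selection
  probabilities, normalized to mean 1 so weighted and unweighted n are
  comparable.
* **Socioeconomic structure:** a household latent asset score (Normal,
  shifted by region and urban residence) replaces the asset-PCA wealth
  index — only quintile formation is methodologically active downstream.
  Weighted quintiles are cut by a cumulative-weight walk (each unit
  labelled by the fifth containing its weight-interval midpoint, ties in
  stable input order, each quintile holding 20% of weight up to one
  unit). Education probabilities are monotone in the asset score via a
  cumulative-logit draw.
* **Outcome:** Bernoulli with logit = region baseline + Normal PSU
  intercept (`cluster_sd`, default 0.9 ⇒ latent-scale ICC ≈ 0.2, typical
  for immunization outcomes in clustered national surveys) + per-step
  effects of wealth quintile, education, urban residence, sex (default
  0: sex-null), maternal age, antenatal visits, facility delivery and
  birth order.

Default effect sizes and region baselines were fixed once to reproduce
the qualitative pattern of the most recent survey round the package's
bundled tables describe — national coverage near 62%, richest quintile
in the low 80s and poorest in the 40s, urban above rural, strong
regional spread, no sex effect — and are configuration values, not
constants. What the generator does *not* emulate: real regional
population shares or sampling frames, questionnaire nonresponse,
multi-indicator correlation structure, or informative weighting beyond
the design itself. Consequently, passing parameter-recovery and
property tests shows the estimators are correct under a faithful
two-stage design with known effects; it does not validate the published
coverage levels themselves, which require the restricted survey files.

## 7. Numerical choices and test scale

* Quintile ties: stable input order; right-closed weight intervals.
* Logit-scale CIs fall back to one-sided exact bounds at 0%/100%.
* Ridit WLS is solved via the normal equations (2×2 system;
  well-conditioned for any non-degenerate share vector); shares are
  validated to sum to 1 within 0.05 and renormalized.
* Estimate-table validation: CI bounds must bracket the estimate (error
  with row numbers); share sums within 0.005 pass silently, within 0.05
  warn, beyond error.
* All randomness flows from a single integer seed; generation is
  deterministic given the seed, and year labels shift the stream so
  rounds are independent.
* Problem sizes in the test suite were chosen for statistical
  resolution: parameter recovery runs 50 seeds at roughly 10,000
  children in about 700 clusters (median OR within 10% of truth,
  interval coverage near nominal); gradient-sign checks use the default
  ~3,200-child configuration; the bootstrap tests use 40–80 replicates,
  enough to locate percentile endpoints for smooth statistics.

## 8. Known limitations

* The linear-scale SII/RII can extrapolate outside $[0, 100]$; the logit
  variant avoids this but changes the estimand slightly. Neither is
  guaranteed to match toolkit implementations whose estimator is
  unpublished.
* Delta-method CIs from published tables inherit whatever method built
  the published intervals, and treat subgroups as independent (the
  reference-vs-national covariance in PAR is ignored; PAR/PAF intervals
  are therefore approximate).
* The CI-overlap trend rule is conservative and unadjusted for
  multiplicity.
* The multilevel model treats the PSU as the community and ignores
  weights by default; both are stated choices, not discoveries about the
  data.
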