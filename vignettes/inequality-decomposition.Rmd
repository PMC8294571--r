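---
title: "Measuring and decomposing wealth-related inequality in abdominal obesity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and decomposing wealth-related inequality in abdominal obesity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Abdominal obesity — a waist circumference above a sex-specific threshold —
is unevenly distributed across the socioeconomic spectrum. In Peru (and in
many middle-income countries) it concentrates among the *wealthy*, the
opposite of the gradient familiar from high-income settings. `ineqdecomp`
provides the full chain of methods used to quantify such a gradient from
complex-survey microdata: survey-weighted prevalence and direct age
standardization, concentration curves, the concentration index and its
Erreygers correction for binary outcomes, and the Wagstaff–van Doorslaer
decomposition of that index into covariate contributions. A seeded
generator of ENDES-like microdata (the Peruvian Demographic and Family
Health Survey is the template) makes every stage testable without access
to restricted survey files.

## Ranks, curves, and indices

All inequality measures rank respondents by a continuous household wealth
score (in ENDES, a principal-components asset index built upstream by the
statistics institute; the package takes the score as given). The
**weighted fractional rank** of record $i$ is the Lerman–Yitzhaki
midpoint:

$$R_i = \sum_{j: x_j < x_i} w_j + \tfrac{1}{2}\sum_{j: x_j = x_i} w_j,$$

with weights normalized to sum to one. Ties share a single rank, which
keeps the weighted mean of $R$ at exactly $1/2$; ranks depend on wealth
only through its ordering, so every downstream index is invariant to
strictly monotone transforms of the score and to positive rescaling of the
weights (both are tested properties).

The **concentration index** is twice the weighted covariance of outcome
and rank, scaled by the outcome mean $\mu$:

$$CI = \frac{2}{\mu}\,\mathrm{cov}_w(y, R) \in [-1, 1],$$

positive when the outcome concentrates among the wealthy. For a binary
outcome the attainable range of $CI$ shrinks as $\mu \to 1$, which makes
comparisons between groups with different prevalences (here: men at
roughly 0.6, women at roughly 0.85) misleading. The **Erreygers index**
removes that dependence:

$$ECI = \frac{4\mu}{b_n - a_n}\,CI = 8\,\mathrm{cov}_w(y, R)
\quad\text{for } (a_n, b_n) = (0, 1).$$

The **concentration curve** plots cumulative weighted outcome share
against cumulative population share in wealth order; $CI = 1 - 2\,AUC$
with trapezoidal area on the record-level curve, an identity the test
suite checks to $10^{-6}$.

### Standard errors

The published sources in this literature rarely name their SE estimator.
The package's default is the *convenient regression*: the WLS slope of
$2\sigma^2_R\, y_i/\mu$ (or $8\sigma^2_R\, y_i$ on the Erreygers scale) on
$R_i$ equals the index, so its heteroskedasticity-robust (HC1) standard
error estimates the index SE. When PSU identifiers are present,
`cluster_robust` clusters the same sandwich on PSU. The convenient-
regression SE is validated against a 500-replicate bootstrap (agreement
within 10% at $n = 5{,}000$) and against the $1/\sqrt{2}$ scaling under
record duplication.

### Degenerate inputs

$\mu = 0$ leaves $CI$ undefined and raises an error rather than returning
`NaN`; $\mu = 1$ (binary) gives zero covariance, so $CI = 0$ is returned
with a degeneracy flag. Equal outcome bounds are an error for the
Erreygers index. Single-record cells report an `NA` standard error.

## Survey machinery

**Eligibility.** Records are filtered in a fixed order — minimum age
(the boundary age is eligible), pregnancy, missing waist — and each
exclusion is counted once under the first rule that removes it, so the
counts reproduce a recruitment flowchart.

**Pooling.** When two survey rounds are pooled, their expansion factors
live on different population totals. The default
(`per_year_normalized`) rescales each year's weights so the year's weight
total equals its unweighted sample size: each round then influences pooled
estimates in proportion to its information content rather than its
expansion total, which would otherwise let one year dominate. `as_is` is
available for already-harmonized weights; with a single round both
policies coincide up to a global scale that no estimate depends on.

**Quintiles.** Weighted quintile boundaries sit at cumulative weight
fractions 0.2…0.8 of the wealth-sorted population. A record whose mass
straddles a boundary is assigned to the quintile containing its weight
midpoint (its fractional rank), with exact-boundary midpoints going to the
lower quintile; tied wealth scores share a quintile. Fewer than five
distinct wealth values produce a degenerate-quintiles warning, not an
error.

**Variance for prevalences and means.** With `psu`/`stratum` columns the
package uses Taylor linearization of the ratio mean, totalling score
residuals within PSU and taking the with-replacement between-PSU variance
within each stratum; without design columns every record is its own PSU.
Intervals for proportions are formed on the logit scale so they stay
inside $(0,1)$; a Wilson interval on the Kish effective sample size is the
config-selectable alternative. Which method produced an interval is
recorded in the output.

**Age standardization.** Direct standardization against the WHO world
standard population (2001, five-year bands, shipped as a plain-text file
and normalized to sum to one). Because published comparisons typically use
coarse adult bands, `who_standard_population(breaks = c(18, 30, 60))`
collapses the five-year bands onto analysis bands by summing the standard
weights at or above the first break and renormalizing. The choice of
banding is configuration, not hard-coded: published adult analyses do not
always state their band-merge, so standardized levels are reproducible in
method but not necessarily in value.

## The decomposition

For a binary outcome modelled by a survey-weighted logistic GLM on
dummy-coded covariates, the Erreygers index decomposes as

$$ECI = \sum_k 4\,\beta^m_k\,\bar x_k\,CI_k \;+\; 4\,GCI_\varepsilon,$$

where $\beta^m_k = \beta_k\,\bar p(1-\bar p)$ is the **marginal effect at
means** (the fitted density evaluated at the weighted covariate means —
not the average marginal effect), $\bar x_k$ the weighted dummy mean,
$CI_k$ the plain concentration index of the dummy over the *same* ranks
as the total index, and $GCI_\varepsilon$ the generalized concentration
index of the model error. Design choices worth stating explicitly:

* **The factor 4 is folded into the reported elasticity**
  ($\text{elasticity}_k = 4\beta^m_k \bar x_k$), so each row satisfies
  `contribution = elasticity × ci_k` and rows plus residual sum to the
  total ECI. This is the only scaling under which the published reference
  table's row products and its men's adding-up identity both hold, so the
  package adopts it as the table convention.
* **$CI_k$ is the plain (uncorrected) concentration index of the dummy**,
  not an Erreygers-corrected one: the Erreygers scaling enters once,
  through the elasticity.
* **The residual is reported twice**: as the exact closure
  `total_eci - sum(contributions)` (used by `validate_adding_up()`, zero
  gap by construction) and as $4 \times GCI$ of $y - \hat y$, a diagnostic
  that should approximately agree with the closure when the model is well
  specified. On synthetic data generated from the same logistic family
  *with wealth quintiles among the regressors* the residual stays below
  10% of the total; omitting the wealth terms moves the direct wealth
  gradient into the residual, which is the correct accounting, not a
  defect.
* **Weights are used in the GLM** (normalized to mean one, quasibinomial
  family so non-integer weights fit cleanly); an identity-link binomial
  is available behind the `link` argument for sensitivity analysis.
* **Ranks are recomputed within each analysis subgroup** (default:
  within sex). Indices are published per sex, and a within-sex index
  should measure the wealth ordering *among* that sex; ranking on the
  pooled sample remains available via `rank_scope = "pooled"` in the
  pipeline configuration.

### The published worked example

`reference_decomposition()` ships the published per-sex decomposition
estimates for Peruvian adults (pooled ENDES 2018–2019; IDF definition) as
a plain-text table: elasticities, level concentration indices,
contributions, percent contributions, residuals, and totals (0.342 men,
0.082 women). The acceptance script recomputes the identity columns from
the printed elasticity and index columns: every contribution matches to
±0.001, the men's contributions plus residual close exactly on 0.342, and
percent contributions match to ±0.2 points for all men's rows. Two
women's rows (richest, urban) reproduce only against an unrounded women's
total near 0.083 — the printed two-decimal total is too coarse for its
own percent column — and the women's printed residual (−0.280) does not
close the women's identity at all; both facts are surfaced by the checks
rather than patched.

## The synthetic generator

`synthetic_design()` emulates what matters for this methodology, with
defaults chosen once to mirror the pooled 2018–2019 Peruvian adult
population:

* a continuous wealth score (standard normal by default; the outcome
  model consumes only its *rank*, so the score's shape is irrelevant by
  construction — the estimand is rank-based and the generator respects
  that);
* gamma(shape 4, scale 0.25) expansion-factor noise (mean 1, mild
  realistic dispersion), a constant-weight mode for oracle checks, and a
  stratified design mode that adds PSU-level wealth shifts for exercising
  cluster-robust variance;
* eight categorical covariates (age band, marital status, education,
  natural region, urban/rural, altitude band, chronic disease, smoking)
  with marginal shares near the published population and a single
  proportional-odds wealth slope each — education, urban residence and
  metropolitan region concentrate among the wealthy, altitude among the
  poor;
* a logistic outcome with sex-specific intercepts and wealth-rank slopes
  (defaults calibrated to prevalences near 0.61 in men and 0.85 in women
  with a much steeper male gradient, the qualitative signature of the
  Peruvian data);
* an optional per-sex normal waist circumference whose mean rises with
  wealth rank (gradients ≈ 11 cm in men, 4 cm in women across the rank
  range), so cut-off classifiers and criterion comparisons can run on
  generated data; and
* per-component seeded streams (a string-hash offset of one global seed),
  so adding a covariate never perturbs the other draws and identical
  designs are bit-identical.

What it does **not** emulate: real nonresponse and calibration weighting,
the two-stage sample selection of the actual survey, inter-covariate
dependence beyond the shared wealth gradient, and any attempt to match
the real marginal distributions exactly. Tests that pass on this
generator therefore validate the *estimators* (bias, invariances,
coverage), not the fidelity of any particular national estimate.

`true_eci_by_simulation()` is the ground-truth device: one very large
draw (default $10^6$) from the same design on a dedicated seed stream,
whose ECI serves as the oracle for recovery tests.

## Validation scale

The recovery studies run at the sizes a desk machine handles in minutes,
chosen as the package's own validation conditions: oracle populations of
$10^6$; 100 seeded replicates of $n = 50{,}000$ for index recovery across
gradient strengths (oracle ECI ≈ 0, 0.1, 0.33); 100 replicates of
$n = 20{,}000$ for dominant-covariate recovery in the decomposition; a
500-replicate bootstrap at $n = 5{,}000$ for the SE comparison. Estimates
are required to cover their oracle within three Monte-Carlo standard
errors in at least 95% of replicates.

## Known limitations

* Standard errors treat the convenient-regression representation as exact
  and ignore the sampling variability of $\mu$ and of the ranks; this is
  standard practice but slightly anticonservative in small samples.
* The decomposition's marginal effects at means inherit the usual caveat
  that the mean covariate vector describes no actual person; average
  marginal effects are not currently offered because the reference
  convention is MEM.
* Dominance testing between concentration curves, generalized/Wagstaff
  indices beyond CI/ECI, and Oaxaca-style decomposition of between-sex
  differences are out of scope.
* The Taylor variance assumes with-replacement PSU sampling within strata
  (the standard large-population approximation); finite-population
  corrections are not implemented.
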