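---
title: "Methods: attendance modelling and zero-loss penalty pricing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attendance modelling and zero-loss penalty pricing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noshowpricing)
```

# Setting

An outpatient department books `nt` patients per period. Some fraction do
not show up; personnel costs are fixed, material costs accrue only for
patients actually treated, and a non-profit operator wants the period to
end at exactly zero loss. The package couples three analyses: a screen of
which appointment covariates drive attendance, classifiers that predict
attendance, and a pricing model that converts a classifier's show-up rate
into a break-even penalty fee for no-show patients who rebook.

# The synthetic cohort generator

## Outcome model

Real attendance tables are rarely shareable, so the package states an
explicit synthetic world. Each of the 13 covariates is drawn
independently at configurable marginals; the outcome is Bernoulli with a
logistic link,

$$\Pr(\text{show-up}) = \operatorname{logit}^{-1}\Big(\eta_0 + \sum_j \beta_j x_j\Big).$$

This is deliberately the *simplest* data-generating process consistent
with the qualitative effect pattern the analysis targets: a dominant SMS
reminder effect; moderate age, weekend, season, vehicle, health-issue and
residence-zone effects; and null gender, insurance, companion,
citizenship, treatment-change and department effects. A categorical block
(department, residence zone) enters through a fixed sinusoidal
level pattern scaled by a single coefficient, so "the block matters" is a
one-number dial while its levels stay deterministic. The calendar date
enters only through the seasonal score $\sin(2\pi\,\text{doy}/365.25)$;
the weekend flag is derived from the drawn date, not sampled.

## Default parameters and why

| parameter | default | rationale |
|---|---|---|
| cohort size | 1073 | reference cohort scale (706 female, 367 male) |
| gender split | 706/1073 | printed split |
| department weights | 111,124,126,113,104,123,118,137,117 / 1073 | printed per-department counts |
| residence zones | 66 | the zone block's published degrees of freedom |
| age | truncated normal, mean 45, sd 18, range 0–95 years | no distribution is published; a broad adult outpatient mix |
| intercept | −0.95 | gives ≈55% show-up, matching the published test-set class balance (121/214) |
| SMS reminder | +2.5 log-odds | the dominant factor by an order of magnitude |
| age | +0.025 per year (centred at 45) | see power note |
| weekend | −0.9 | see power note |
| own vehicle / health issue / season / zone | +0.35 / −0.45 / 0.3 / 0.4 | moderate effects, odds ratios ≈ 0.6–1.5 |
| null factors | 0 exactly | gender, insurance, companion, citizen, treatment change, department |

**Power note.** The factor screen is validated on 50 replicate cohorts at
n = 1073 and must recover SMS, age and weekend essentially always. Effect
sizes were fixed *once*, before the validation was frozen, by a
noncentral-F power computation targeting per-replicate power ≥ 0.999 at
α = 0.05 (noncentrality ≈ 25–30 for age and weekend given the model's
residual variance ≈ 0.17); SMS is far beyond that. They were not adjusted
afterwards.

## What the generator does not emulate

Covariates are independent (no age–department or zone–vehicle
correlation); there are no repeat visits by the same patient, no
per-department outcome differences, no calendar trends beyond one
seasonal harmonic, and no missing data. A green test on this world
establishes that the *pipeline machinery* is correct — recovery of
planted effects, calibrated error rates under the null, correct
arithmetic everywhere — not that any particular hospital's attendance
behaves this way.

# Classifiers

No tree-ensemble package is assumed; a weighted CART learner (squared
error impurity, equivalent to Gini for 0/1 responses) is compiled from
`src/tree.cpp`, and the three ensembles are built on it:

* **RF** — bootstrap aggregation with per-node feature subsampling
  (`max_features` of `sqrt`/`log2`/count), averaging leaf show-up
  fractions across trees.
* **GB** — stagewise logistic-loss boosting: each tree fits the residual
  `y − p`, then each leaf takes one Newton step
  `Σ(y−p)/Σ p(1−p)`, scaled by the learning rate; optional row
  subsampling.
* **AB** — discrete AdaBoost with depth-1 stumps; the reported score is
  the weighted vote share for show-up, so thresholding at 0.5 equals the
  weighted majority vote. Boosting stops early on a perfect or
  worse-than-chance stump.

Departments and residence zones are one-hot encoded against the training
levels; an unseen zone at predict time is an explicit error rather than a
silent zero column. Splits are stratified with largest-remainder
allocation, so the test set size is exactly `round(n·f)` and each class
is within one count of its proportional share. Tuning is exhaustive grid
search under stratified k-fold CV (default k = 5; accuracy scoring,
switchable to AUC), with deterministic first-wins tie-breaking; the
default split is 70/30 (an 80/20 preset matches the published test-set
size of 214 ≈ 20% of 1073). All randomness — fold assignment, bootstraps,
feature subsampling — flows through one seed per model spec.

# Evaluation conventions

* A single printed value per metric summarises two classes as the
  **support-weighted average** of the per-class values (weights = actual
  class sizes). This is the only convention under which the published
  counts reproduce the published precision/recall/F1, and it makes
  weighted recall identically equal to accuracy.
* Confusion-matrix percentage tables are normalised **by predicted-class
  column**: `alpha = tn/(tn+fn)`, `beta = tp/(tp+fp)`. `beta` — the
  positive predictive value of show-up predictions — is the show-up rate
  the pricing model consumes.
* Zero-denominator metric cells return 0 with a warning rather than
  erroring, so batch evaluation of degenerate folds never aborts. MCC is
  computed in double precision (the four-margin product overflows 32-bit
  integers near n ≈ 10³).
* ROC curves group tied scores into single vertices; the trapezoidal AUC
  then equals the Mann–Whitney statistic `U/(n₊n₋)` exactly, which the
  tests assert. Calibration curves use equal-width bins on [0,1] with
  empty bins omitted.

# The ANOVA screen

The screen is a **linear probability model** of the 0/1 outcome with
adjusted (Type-III / partial) sums of squares: each factor's SS is the
residual-SS increase from dropping that term from the full model, tested
against the residual mean square with a partial F test. Date enters as
its 1-df seasonal score; department and zone as categorical blocks (8 and
65 df with an intercept — the published table's "66" reflects a different
parameterisation and its "Departments 1" is not reproducible). Because
covariates are drawn independently, Type-II and Type-III coincide here.
The binary response makes the LPM heteroscedastic; at the cohort sizes
used (≥ 1073) the F-test p-values are nevertheless uniform under the
null to Kolmogorov–Smirnov precision, which the acceptance suite checks
on pooled p-values over 200 null cohorts. Significance uses the rule
p ≤ α (boundary inclusive), α = 0.05 by default, with no multiplicity
correction — matching the screening convention the analysis mirrors.

# The pricing model

With `nn = nt − ns` vacated slots and classifier show-up rate β, the
expected refill is `nnr = nn(1−β)β` penalised reappointments and
`nsn = nnβ²` new patients, so `nnr + nsn = nnβ ≤ nn` always. Revised
revenue and the break-even fee are

$$R_r(\varphi) = n_s(P_f-c_m) + \beta^2 nn (P_f-c_m) + (\beta-\beta^2)\,nn\,(\varphi-c_m) - c_p,$$
$$\varphi^\* = c_m + \frac{c_p - \big(n_s + \beta^2 nn\big)(P_f-c_m)}{\beta(1-\beta)\,nn}.$$

The closed form is obtained by solving the zero-loss condition
symbolically (the published closed form is typographically corrupted; the
solved form is verified by plug-back to 10⁻⁹ relative tolerance over 10⁵
random parameter draws). It is undefined when β ∈ {0, 1} or there are no
no-shows — the φ coefficient vanishes — and this is an error, not a
default.

**Sign regimes.** φ* is reported unclamped with flags: below the material
cost (`phi < cm`, a subsidy regime — refilled standard-fee revenue
already overshoots break-even) or above the standard fee. Differentiating
the closed form gives

$$\frac{\partial\varphi^\*}{\partial n_s} = \frac{-E_r}{\beta(1-\beta)\,nn^2},
\qquad E_r = n_t(P_f-c_m)-c_p,$$

so the fee falls with attendance exactly when the full-attendance period
is profitable, and *rises* with attendance in a structural-loss regime —
the property tests assert this sign law, not an unconditional
monotonicity. φ* is strictly increasing in `cp` unconditionally.

**Horizon simulator.** Per day: demand `nt_d ~ Poisson(11)` (≈1073
patients per 100 days), a no-show fraction drawn uniformly on
`(0, r_max]` with `r_max = 1 − β` per algorithm, and
`ns_d = floor(nt_d(1−u_d))`. The floor guarantees at least one no-show on
every demand day; with rounding instead, `r_max ≈ 0.025` would make
almost every Poisson-11 day contribute nothing. Days without demand
contribute no rate; an all-empty horizon is an error. The default
personnel cost is the break-even value at mean demand
(`cp = E[nt](Pf−cm) = 880`); none of these operational constants are
published, so all are configurable and recorded in run artifacts.
Algorithms simulated under one seed share identical demand and
no-show-quantile draws, so cross-algorithm differences isolate β. The
penalty *rate* is `100·φ/Pf`, averaged arithmetically over contributing
days. Repeat offenders can be escalated with a multiplier sequence
(default 1, 1.5, 2, last value held) — the mechanism is published without
numbers.

Because the day-level cost/demand inputs behind the published average
rates (22.87% / 19.47% / 14.28% for RF/GB/AB) are not printed, those
numbers are *not* reproduction targets; the package's validated claim is
structural — zero-loss identity, refill bound, formula equivalence, the
worked example φ = 60, and the β-ordering (a lower-β classifier yields a
lower average rate in a shortfall regime), mirroring the published
AB < RF ordering. The published RF/GB rate difference at identical
β = 0.975 depends on an undisclosed differentiating input and is likewise
out of scope.

# Numerical and degenerate-input choices

* All stochastic entry points take explicit integer seeds via
  `withr::with_seed`, so library state is never mutated.
* CART splits at midpoints of consecutive distinct values; node impurity
  below 10⁻¹² stops splitting; tie-breaks favour the first feature in
  column order (after the per-node `mtry` draw).
* GB leaf Newton denominators are floored at 10⁻¹⁰; AdaBoost caps the
  weight of a perfect stump at 10.
* Grid ties: first configuration in cross-product enumeration order.
* Schema validation errors name the offending column and first offending
  row; pipeline stage failures name the stage.

# Limitations

The generator's independence and single-harmonic assumptions above; the
LPM screen (not a logistic deviance ANOVA — chosen to match the
adjusted-SS regression-ANOVA convention of the mirrored table); ensemble
implementations favour clarity over the micro-optimisations of dedicated
libraries and are validated behaviourally (separable cohorts, null
convergence to the majority rate, seed determinism) rather than
bit-compared to any reference; and the pricing model treats refill
expectations as deterministic day-level quantities rather than modelling
refill stochasticity.
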