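---
title: "Mapping CAT scores to EQ-5D-3L utilities: models, fitting and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping CAT scores to EQ-5D-3L utilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cat2eq5d)
```

## The problem

Cost–utility analyses need preference-based utilities, but COPD trials
and clinics usually administer the COPD Assessment Test (CAT): eight
items (cough, phlegm, chest tightness, breathlessness, activities,
confidence, sleep, energy), each scored 0–5, total 0–40, higher = worse.
The EQ-5D-3L describes health by five dimensions (mobility, self-care,
usual activities, pain/discomfort, anxiety/depression) at three levels,
and a country-specific value set ("tariff") converts each of the
$3^5 = 243$ states to a utility anchored at 1 (full health) and 0
(dead), with negative values allowed. `cat2eq5d` implements mapping
("crosswalk") algorithms that predict EQ-5D-3L utilities from CAT
responses, plus the machinery to refit and validate them on
repeated-measures clinic data.

## The tariff

The Taiwanese time-trade-off value set is built in. For a state other
than (1,1,1,1,1) the utility is

$$u = 1 - 0.185 - \sum_{d} \delta_d(\ell_d) - 0.190\,[\exists d: \ell_d = 3],$$

with per-dimension decrements $\delta_d$ at level 2 / level 3 of
0.123/0.272 (mobility), 0.167/0.276 (self-care), 0.085/0.208 (usual
activities), 0.121/0.261 (pain/discomfort) and 0.154/0.282
(anxiety/depression). Read literally the formula subtracts the constant
0.185 from every state; observed data, however, contain utility exactly
1, so full health is treated as the anchor and the constant applies only
to non-full-health states. `utility_from_state(..., literal = TRUE)`
evaluates the verbatim formula for audit. The "any level 3" decrement is
an indicator, applied once. Over all 243 states the range is
$[-0.674, 1]$ and worsening any single dimension never increases the
utility:

```{r tariff}
u <- utility_from_state(all_eq5d_states())
range(u)
```

## The mapping models

Four algorithm families sit behind one `model_spec` interface
(`builtin_model_names()` lists the frozen published equation sets):

* **Response mapping (`mlr_response`)** — for each EQ-5D dimension a
  three-level multinomial logit with level 1 as baseline,
  $p_k = e^{\eta_k} / (1 + e^{\eta_2} + e^{\eta_3})$, evaluated by
  log-sum-exp so the published coefficients of several hundred in
  magnitude saturate cleanly instead of overflowing. The predicted level
  is the probability argmax (ties go to the healthier level — a
  deterministic, conservative rule), and the predicted state is scored
  with the tariff, so predictions always lie in the 243-value tariff
  set. Two variants are built in: `taiwan_mlr_total` (CAT total, age,
  sex) and `taiwan_mlr_items` (backward-selected items per dimension).
* **Direct OLS (`direct_ols`)** — a single linear equation on items or
  the CAT total (the Hoyle M3 and Lim forms, original and
  re-estimated). Predictions are *not* clamped to $[0,1]$: the
  re-estimated equations print maxima of 1.04–1.12, so the source
  analyses clearly did not clamp.
* **Two-part (`two_part`)** — classify into utility groups (exactly 1 /
  middle / low) by two logistic-style expressions sharing slopes, then
  apply the selected group's outcome equation. The expressions are
  evaluated *exactly as printed*, including the re-estimated variant's
  middle denominator, which reuses the top intercept; the three values
  then need not sum to one, and because the middle expression shares
  slopes with the top one but has a larger intercept, the utility-1
  group is never the maximum. That literal pathology is intentional —
  it reproduces the published behaviour (a maximum prediction of 0.79
  for the original form) and the documented downward collapse on
  near-healthy cohorts. `canonical_ordinal = TRUE` substitutes the
  coherent cumulative-logit construction
  ($p_{top} = \mathrm{expit}(\eta_{top})$,
  $p_{top}+p_{mid} = \mathrm{expit}(\eta_{mid})$) for sensitivity
  analysis; under it the top group is reachable again.
* **Mean Rank Method (`mrm`)** — nonparametric equating: a CAT total
  and a utility are matched when they hold the same mean rank in their
  training samples. Ties share the mean of their rank positions; the
  mean rank $\bar r$ of a CAT total maps to the percentile
  $p = 1 - (\bar r - 0.5)/n$ (complemented because higher CAT is worse)
  and to the lower-step empirical quantile of the utility sample at
  $p$. Unseen CAT totals are linearly interpolated between knots and
  clamped at the extremes. The quantile type, interpolation and
  clamping are this package's choices — the method's sources specify
  only the rank-matching concept — and are isolated behind
  `build_mrm_table()` so alternatives can be swapped.

```{r predict}
nd <- data.frame(cat_total = c(0, 18, 30), age = 65, sex_code = 0)
predict_utility_mlr("taiwan_mlr_total", nd)
```

A note on the sex covariate: the published equations include a 0/1 sex
term whose direction is not defined by its source. The data format uses
`sex_code` with a documented default of male = 1; predictions from
models with large sex coefficients are sensitive to this coding, and
data prepared under the opposite convention must be recoded.

## Fitting machinery

`fit_mnl_independence()` refits a dimension's multinomial logit on
repeated-measures data by pooled maximum likelihood with a
cluster-robust (sandwich) covariance, scores summed within patients.
Under an independence working correlation the GEE estimating equations
coincide with the pooled score, so this reproduces GEE point estimates
while the sandwich absorbs within-patient dependence; only the robust
covariance is available under that contract, which is why elimination
uses Wald rather than score or likelihood-ratio tests. Newton–Raphson
with step halving runs to a gradient max-norm below $10^{-8}$ (at most
100 iterations); quasi-separation is flagged when any coefficient
magnitude exceeds 50 (configurable) and a tiny ridge keeps the ascent
direction defined if saturation flattens the information. If a level
never occurs, its logit is pinned at $-\infty$ (probability zero) and
flagged rather than failing.

`backward_eliminate()` repeatedly removes the covariate with the
largest joint Wald p-value above $\alpha = 0.05$, testing the two logit
coefficients together (2 df). Testing them jointly rather than one
logit at a time is a design choice: a covariate is kept if it helps
predict either elevated level; the per-logit alternative would let a
covariate survive on one logit while dead weight in the other.

`qic()` returns
$\mathrm{QIC} = -2\,QL + 2\,\mathrm{trace}(\hat\Omega_I \hat V_R)$ with
$QL$ the multinomial log-likelihood under independence, $\hat\Omega_I$
the model-based information and $\hat V_R$ the robust covariance; with
independent clusters the penalty tends to twice the parameter count and
QIC approaches AIC. `fit_ols()` regenerates the "re-estimated" direct
mappings by least squares.

## Validation toolkit

`mae()`/`rmse()` are observation-level (every visit weighted equally,
matching validation tables whose N counts observations, not patients).
`subgroup_report()` tabulates N, mean/min/max prediction, MAE and RMSE
for the full set and for three partitions: severity stage 1/2/3 (stage
3 = FEV1 < 50% predicted, the merged severe group), observed-utility
bands (lower-inclusive; top band closed, so utility 0.75 counts as
$\ge 0.75$; the bottom band is open below so rare worse-than-dead values
still land in a band) and CAT bands 0–10 / 11–20 / 21–30 / 31–40
(inclusive integer ranges). `bubble_grid()` bins predicted against
observed utilities on $[-0.7, 1]$ (half-open bins of width 0.05, final
bin closed) — the data behind a calibration bubble chart, where a good
model concentrates mass on the diagonal; `plot()` renders it with base
graphics.

## The synthetic cohort generator

No patient-level data ship with the package, so `simulate_cohort()`
generates a cohort with the structure of a Taiwanese COPD clinic
population followed under a disease-management program: 323 patients,
visit counts 1–16 from a truncated negative binomial (mean ≈ 7.2,
about 2,327 observations), a patient-level latent severity shared by
all of a patient's visits plus visit-level noise, CAT items produced by
thresholding severity (plus item noise) against common ordinal cut
points, and the EQ-5D-3L state *sampled* from the built-in total-score
response-mapping model at each visit's CAT total, age and sex, then
scored with the tariff. Severity stage (1/2/3) is assigned from the
patient's latent severity at the cohort's stage proportions.

Design choices worth knowing:

* **Latent severity is right-skewed** (standardized gamma, shape 0.8):
  many mild patients and a thin severe tail, which is what produces the
  strong negative utility–CAT correlation alongside a high mean
  utility.
* **Balanced enrolment.** By default patient severities, ages, sexes
  and visit counts are drawn on their distributions' quantile grids and
  randomly assigned to patients (`sev_sampling = "quantile"`). A
  323-patient cohort redrawn i.i.d. wanders visibly in its summary
  statistics from enrolment noise alone; the emulated study is one
  fixed cohort, so the generator holds the composition and randomizes
  everything else. `sev_sampling = "random"` restores i.i.d. draws.
* **Calibration is frozen.** The free parameters (thresholds, severity
  and noise scales, age distribution centred at 63.5 years, 12%
  prevalence of the sex coded 1) were calibrated once against the
  cohort's published marginal statistics — mean utility 0.917, mean CAT
  9.88, utility–CAT correlation −0.69, 69.79% of observations at
  utility 1, 2,327 observations — and are not meant to be re-tuned.
  The achieved mean utility centres near 0.894, inside the calibration
  band but below the printed value: with the published response-mapping
  model acting as the generator, departures from full health involve
  two or more dimensions somewhat more often than in the raw cohort, so
  the affected states average lower. This is a structural property of
  sampling states from that model under conditional independence across
  dimensions, not a tuning residue.
* **What the generator does not emulate:** measurement noise between
  instruments (the utility column is exactly the tariff of the sampled
  state), exacerbations, dropout, treatment effects, or any real
  within-dimension correlation beyond what the shared covariates
  induce. Tests that pass on this cohort certify the algorithms and
  their contracts, not clinical performance on real patients.

```{r cohort}
obs <- simulate_cohort(seed = 1)
c(n = nrow(obs), mean_u = round(mean(obs$utility), 3),
  mean_cat = round(mean(obs$cat_total), 2),
  corr = round(cor(obs$utility, obs$cat_total), 2))
```

`simulate_from_spec()` is the bare parameter-recovery harness: it
samples dimension levels from any response-mapping spec at supplied
covariates, and is what the fitting tests use to check coefficient
recovery and elimination size.

## Numerical conventions and problem sizes

Probability evaluations use log-sum-exp; argmax ties resolve to the
healthier level or group (top > middle > low); OLS predictions are
unclamped; MRM extremes clamp to the nearest knot; fits converge at
gradient max-norm $10^{-8}$. The test suite exercises parameter
recovery at 2,000 patients × 3 visits over 200 replicates and
elimination size at 400 patients × 3 visits over 400 fits — sizes
chosen so a single-workstation run completes in minutes while leaving
the binomial tolerances meaningful — and checks simulator calibration
on three seeded default cohorts. One identifiability subtlety: under the
built-in total-score coefficients, level 3 is unreachable for the sex
coded 0 in four of the five dimensions ($\eta_3 - \eta_2 < 0$ across
the whole covariate domain), so the level-3 intercept and sex
coefficient are estimable only through their sum; recovery is therefore
assessed on every identifiable coefficient plus that contrast, and fits
near this degeneracy are exactly where the quasi-separation flag
activates.

## Limitations

The comparator coefficients are frozen as printed, including their
pathologies; nothing here re-derives them from their source cohorts.
Only the EQ-5D-3L and the Taiwanese TTO tariff are supported
(alternative 3L tariffs can be plugged in as `tariff_table` objects;
5L and VAS scoring cannot). Validation against the original study's
patient-level error tables is out of reach because that cohort is not
public; the package's evidence is exact worked-example agreement,
exhaustive property checks and parameter recovery on synthetic data.
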