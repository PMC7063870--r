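---
title: "Methods: one-sample Mendelian randomization for check-up cohorts"
author: "uramr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: one-sample Mendelian randomization for check-up cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uramr)
```

## The design

`uramr` implements a one-sample Mendelian randomization (MR) analysis of a
continuous exposure (serum uric acid, µmol/L) on time-to-event outcomes
(incident metabolic syndrome and its four diagnostic components) in a
longitudinal health check-up cohort, instrumented by a single SNP coded
additively (0/1/2 copies of the effect allele).

The instrument assumptions are the usual three: the variant is (i)
associated with the exposure, (ii) independent of the unmeasured
confounders of the exposure–outcome relation, and (iii) affects the outcome
only through the exposure (no horizontal pleiotropy). With one variant,
none of the pleiotropy-robust multi-instrument estimators apply; the
package deliberately implements only the single-instrument Wald ratio and
reports the first-stage F statistic as a strength diagnostic without
gating on it.

## Estimation

**First stage.** `linear_fit()` regresses the age-band-standardized
exposure on allele dose by least squares; the slope `beta1` is the
per-allele shift in SD units. By default the first stage is unadjusted,
and it is re-estimated inside each outcome subcohort, since each subcohort
applies its own baseline exclusions.

**Second stage.** `cox_fit()` estimates the per-allele log hazard ratio
`beta2` for the outcome. The estimator is self-contained: Newton–Raphson
on the Cox partial likelihood started at zero with step-halving,
convergence when the largest score component is below `1e-8` or the
log-likelihood changes by less than `1e-10`, Efron's correction for tied
event times (Breslow selectable), and model-based standard errors from the
observed information. Monotone likelihoods (all events at a covariate
extreme) are reported with `converged = FALSE` rather than a large
arbitrary coefficient. The estimator is verified in the test suite against
brute-force grid maximization of the explicitly coded partial likelihood
on small datasets, and cross-checked against an independent reference
implementation.

**Wald ratio.** `wald_ratio()` combines the two stages as
`beta3 = beta2/beta1` with the first-order delta standard error
`S3 = S2/|beta1|`, which treats `beta1` as fixed. This is the convention
of the underlying analysis, and it is deliberate: with a strong instrument
the neglected `beta1` sampling error is second-order, which
`mr_delta_vs_montecarlo()` demonstrates by simulation — and with a weak
instrument the same function shows the delta SE understating the
Monte-Carlo spread of the ratio and warns. The 95% multiplier is fixed at
1.96 throughout; no multiple-testing adjustment is applied anywhere, since
the pipeline mirrors an analysis that applied none.

**Observational contrast.** For each outcome the pipeline also fits the
direct exposure–outcome Cox model, unadjusted and adjusted for age, the
baseline indicators of the components other than the target outcome, and
the three drug-use flags. Smoking and drinking are not in the default
adjustment set (their prevalence in the target population is too low to be
informative) but can be added by passing covariates to `cox_fit()`
directly.

## Phenotyping and cohort construction

`phenotype()` implements the Chinese Diabetes Society 2004 criteria; the
syndrome requires any three of the four components. Two conventions are
worth stating explicitly:

* *Treatment clauses.* "Previously diagnosed and treated" is operationally
  a drug-use flag; the package uses the flags alone, with no separate
  diagnosis field.
* *Missing postload glucose.* Routine check-ups rarely measure 2-hour
  postload glucose, so a missing value is non-contributory; fasting
  glucose and the treatment flag carry the hyperglycemia definition.

`build_cohort()` takes the first record as baseline, excludes subjects
with fewer than two records, aged ≤ 20, with baseline MetS or
self-reported cardio-/cerebrovascular disease, and (for component
subcohorts) with the target component at baseline. Onset between visits is
interval-censored; the package imputes the right endpoint — the event time
is the first check-up at which the criteria are met — which is the
conservative choice when visit spacing is short relative to follow-up.
Person-years are exact sums of per-subject times, and the exclusion log
accounts for every input subject.

`standardize_exposure()` uses closed–open 5-year bands starting at 20,
with everyone aged 80 or more pooled into one top band; bands with fewer
than two members or zero spread are merged into the nearest populated band
with a warning (an error-on-degenerate policy is available). The sample SD
(divisor n−1) is used. Standardization is idempotent and affine-invariant
within bands, which the property tests assert.

## The synthetic cohort generator

No public data exist for the target cohort, so `sim_config()` +
`simulate_study()` generate cohorts with the statistical structure the
analysis assumes. The defaults *are* the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_subjects` | 1381 | cohort size (all female) |
| age | N(39.5, 12²) truncated to [21, 81] | baseline age, years |
| `effect_allele_freq` | 0.40 | instrument allele frequency |
| `b_g` | 0.23 | per-allele exposure shift, SD units |
| `b_u` | 0.6 | confounder → exposure, SD units |
| `gamma_x` | 0 | causal exposure → log-hazard (the null) |
| `gamma_u` | 0.7 | confounder → log-hazard |
| `ua_mean`, `ua_sd` | 257.33, 52.80 | raw uric acid moments, µmol/L |
| `baseline_hazard["mets"]` | 0.016 /yr | calibrated to ≈ 20 events per 1000 person-years |
| follow-up | annual visits, total 1–5 yr, median 2 | check-up schedule |

Notes on the less obvious choices:

* The allele frequency is not published for the instrument in the target
  population; 0.40 gives a first-stage precision comparable to the
  published `beta1` confidence-interval width.
* The confounder `U` is a single standard-normal composite correlated 0.5
  with age (an age/adiposity proxy). With `gamma_x = 0`, the pair
  `(b_u, gamma_u) = (0.6, 0.7)` induces a non-causal observational hazard
  ratio of roughly 1.4 per SD — inside the 1.3–1.7 range the design
  targets.
* The latent exposure is scaled to unit variance *conditional on age*.
  This is what makes `b_g` land on the analysis scale: the analysis
  standardizes within age bands, so per-allele effects are stated per
  age-conditional SD. A side effect is that the marginal uric-acid SD
  slightly exceeds `ua_sd` whenever the confounder tracks age; with
  `b_u = 0` the marginal moments are exact.
* Event times are exponential given the linear predictor (constant
  baseline hazard, the simplest proportional-hazards-consistent choice);
  a Weibull shape is exposed in the configuration.
* Each of the five outcomes draws its own event time. Visit-level
  laboratory values are back-filled for consistency with `phenotype()`:
  a component active at a visit carries an above-threshold value and
  conversely, and component activations are reconciled so that the third
  component activates exactly at the drawn syndrome time. The
  reconciliation slightly distorts the component processes for the rare
  subjects whose natural third activation would precede the syndrome
  time; with syndrome incidence near 20/1000 person-years this touches a
  negligible fraction of subjects and keeps every record internally
  consistent.
* Baseline component prevalence follows a logistic model on the same
  linear predictor, so baseline covariates are genuinely confounded, and
  the adjusted observational model has something to adjust for.

What the generator does **not** emulate: linkage disequilibrium and
multi-SNP architecture, pleiotropic instrument pathways, measurement error
in the labs, visit-frequency informativeness (visits are missed at
random), secular trends, and male physiology (records are generated
female; the male HDL cutoff is implemented but untested against data).
Passing tests therefore demonstrate the estimators and their composition,
not robustness to these real-data features.

## Numerical and testing choices

* The Cox estimator's grid oracles run on ≤ 10-subject datasets at
  absolute tolerance 1e-4 (grid step 1e-4, refined).
* Parameter recovery uses 800 replicates at n = 5000 for the causal arm
  (`gamma_x = 0.5` with the confounder's outcome path off, isolating
  estimator recovery from hazard-ratio non-collapsibility; the property
  is stated for ≥ 200 replicates and the extra replicates buy Monte-Carlo
  precision on the mean) and 500 replicates at n = 1381 for the
  confounded-null coverage arm. Replicate experiments use the fast
  one-row-per-subject generator (`simulate_survival_cohort()`), which
  shares the latent model with the full longitudinal generator but skips
  visit-level back-filling.
* The Hardy–Weinberg test's type-I error is checked at n = 1381,
  p = 0.4 over 2000 multinomial replicates against the [0.035, 0.065]
  band.
* Dates may enter as decimal years or ISO dates; ISO dates convert at
  365.25 days/year.
* Missing genotype or covariates lead to complete-case deletion with a
  logged count.

## Known limitations

* A single instrument cannot detect or correct pleiotropy; the package
  intentionally stops at the Wald ratio.
* The delta interval ignores first-stage uncertainty. With the default
  instrument strength (first-stage F ≈ 28 at the published precision)
  this is a second-order effect, but for weak instruments the interval is
  anti-conservative — use `mr_delta_vs_montecarlo()` before trusting it.
* Hazard ratios are non-collapsible: even a valid instrument recovers a
  marginally attenuated log hazard ratio when events are common. The
  recovery experiments quantify this at realistic event rates (≈ 4% of
  subjects); at high event rates the Wald ratio should be interpreted as
  a marginal, not conditional, effect.
* Right-endpoint imputation of interval-censored onsets biases event
  times late by up to one visit interval; with annual visits and
  multi-year follow-up the effect on hazard ratios is small but real.
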