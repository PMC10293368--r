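---
title: "Validating hip-fracture mortality risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating hip-fracture mortality risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(hipmort)
```

## The problem

Mortality after hip fracture surgery in the elderly is high — around 6% at
30 days and two thirds at 8 years in typical European cohorts — and several
bedside prognostic scores exist to stratify that risk at admission.
`hipmort` implements three of them exactly as published, together with the
full external-validation battery used to judge such models: discrimination
(AUC), calibration (Hosmer–Lemeshow), clinical usefulness (risk groups with
PPV/NPV) and survival by risk group (Kaplan–Meier). Because patient-level
hip-fracture data are rarely shareable, the package also ships a synthetic
cohort generator calibrated to the covariate prevalences and mortality
pattern of a real 344-patient validation cohort, so that every stage of the
pipeline is exercisable and testable without any data download.

## The three models

Each model maps a patient's covariates to a cumulative score $s$ and then
to a predicted 30-day mortality through a logistic link

$$
P(\text{death by 30 d}) \;=\; \frac{1}{1 + e^{\,a - b\,s}},
$$

with $(a, b)$ equal to $(5.0122,\, 0.481)$ for the NHFS, $(4.79,\, 1)$ for
the model of Holt and colleagues, and $(3.823,\, 1)$ for the HEMA. The
published formulas print the risk as `100/1 + e^[...]` percent; the only
reading of that notation that produces probabilities — and reproduces every
published risk-band edge — is $100/(1 + e^{[\ldots]})$, which is what
`predicted_mortality()` computes. Since $b > 0$, predicted risk is strictly
increasing in the score, so AUCs computed on scores and on predicted
probabilities are identical (a property the test suite asserts).

* **NHFS** — seven variables, integer points, maximum 10: age (66–85: 3,
  ≥86: 4), male sex, haemoglobin ≤10 g/dL, cognitive impairment,
  institutional residence, ≥2 comorbidities, malignancy (1 each). The
  cognitive-impairment flag stands in for the Abbreviated Mental Test Score
  item (AMTS ≤6), a substitution used and reported as acceptable in
  validation practice when the AMTS is not recorded.
* **Holt et al.** — six variables with 23 subdivisions carrying signed
  two-decimal regression coefficients; scores are real numbers and can be
  negative (female −0.65, one walking aid −0.02). Rehabilitation shares the
  long-term-care coefficient (0.53) as published.
* **HEMA** — nine variables scored in half-point steps (0.5–2), maximum 12:
  age ≥85, in-hospital fracture, malnutrition, myocardial infarction,
  congestive heart failure, pneumonia, renal disease, malignancy, serum
  urea >9 mmol/L.

Risk groups follow the published cut-offs (`classify_risk()`): NHFS ≤3 /
4–5 / ≥6; Holt <1 / 1–2 / >2; HEMA ≤1 / 1.5–2 / ≥2.5. Two boundary
decisions deserve mention. The Holt bands are printed with open low and
high boundaries (`< 1`, `> 2`), so scores of exactly 1 and exactly 2 belong
to the intermediate band. HEMA scores strictly inside (1, 1.5) or (2, 2.5)
are unreachable under half-point granularity; `classify_risk()` treats them
as an error rather than silently assigning a band, because they can only
arise from a scoring bug upstream. Age bands are inclusive integer-year
bands and age is truncated to completed years before banding (85.9 scores
as 85).

The scoring tables also ship as human-readable JSON under
`inst/extdata/models/`; a test diffs the code-embedded constants against
the shipped files so that neither can drift.

```{r}
model_definition("NHFS")
round(100 * predicted_mortality("NHFS", c(3, 4, 5, 6)), 1)
```

## Missing data

Missing values are scored as negative, not imputed, mirroring bedside use
of these scores (`apply_missing_policy()`): absent flags become `FALSE`,
absent comorbidity counts 0, absent ASA the baseline class, absent
residence/mobility the baseline category, and absent laboratory values stay
`NA` so their threshold rules never fire. Age, sex and fracture type have
no defensible baseline and are required. Every substitution is logged and
surfaces in the validation report's metadata, and the test suite asserts
the policy can never increase any model's score relative to the same record
with the field present and positive.

## Outcomes, horizons and survival

Three horizons are assessed: 30 days, 1 year (365 d) and 8 years,
operationalised as 2922 days (365.25 × 8; the day count is a package
convention since fixed-day and calendar-anniversary definitions differ by
at most two days over 8 years). Death on the horizon day counts as death
*within* the horizon. A patient whose follow-up ends before a horizon with
no recorded death is `unknown` at that horizon and is excluded from that
horizon's mortality denominator and from its discrimination, calibration
and predictive-value computations — but still contributes censored
time-at-risk to the Kaplan–Meier estimate, which is standard survival
practice. Product-limit estimation delegates to `survival::survfit()`;
`km_by_risk_group()` partitions the cohort by a model's risk groups and
omits an empty group with a warning.

## The validation battery

All measures are computed from first principles on top of base R:

* **AUC** (`auc_rank()`) uses the Mann–Whitney midrank formulation, ties
  counted one half; the test suite verifies exact agreement with
  brute-force enumeration of all case–non-case pairs on instances up to
  n = 50.
* **Confidence intervals and model comparison** use the DeLong
  placement-value variance and the paired DeLong test
  (`compare_auc_paired()`). The source study names neither its CI nor its
  comparison method; DeLong is the field standard for correlated ROC
  curves on the same patients, and the implementation is cross-checked
  against `pROC` in the tests. CI bounds are clipped to [0, 1].
* **Hosmer–Lemeshow** (`hosmer_lemeshow()`) groups patients by deciles of
  predicted risk (ties never split), and sums
  $(O_k - E_k)^2 / (n_k \bar p_k (1 - \bar p_k))$ over groups — the
  classical statistic covering both the death and survival cells. When
  predictions take fewer distinct values than requested groups (inevitable
  with integer NHFS scores), groups are merged and the degrees of freedom
  adjusted, with a warning.
* **PPV / NPV** (`predictive_values()`): probability of death in the
  high-risk group and of survival in the low-risk group.

### Degrees of freedom for the Hosmer–Lemeshow test

The default reference distribution uses $g - 2$ degrees of freedom, the
convention of the original test and of most software. That convention is
derived for the *development* setting, where the probabilities were fitted
on the same data. In external validation the predictions are fixed in
advance, each group's standardised deviation is asymptotically standard
normal, and the statistic is chi-square with $g$ degrees of freedom;
referring it to $g - 2$ roughly doubles the nominal 5% rejection rate
(≈0.11 in our simulations). `hosmer_lemeshow()` therefore exposes `dof`:
the default stays at the conventional $g - 2$ for comparability with
published tables, and the package's own calibration simulations (and the
acceptance checks) use `dof = g`, the correct reference for externally
fixed predictions. Both choices are reported alongside the statistic so a
reader can recompute either p-value.

## The synthetic cohort generator

`generate_cohort()` emulates the *marginal* structure of a surgically
treated hip-fracture cohort; it does not attempt the joint distribution
beyond two documented dependence knobs. Defaults reproduce the published
prevalences of every scored variable (e.g. 29.7% male, 33.1% age ≥86, 7.0%
haemoglobin ≤10 g/dL, 18.6% cognitive impairment, 19.8% institutional
residence, 33.7% with ≥2 comorbidities, 17.2% malignancy, 28.2% ASA 3,
58.7% extracapsular fracture, 8.7% urea >9 mmol/L) and the published
mortality pattern (6.1% / 19.1% / 68.6% at the three horizons) at the
published cohort size n = 344.

Design choices worth knowing:

* **Age** is drawn from a piecewise-uniform distribution over integer
  years with knots at 60/66/70/80/85/86/90. The segment masses are the
  unique solution reproducing *simultaneously* the NHFS bands
  (.212/.456/.331), the five Holt bands (.125/.140/.189/.372/.174) and the
  HEMA ≥85 prevalence (.372); the implied median age is 81 years, which was
  not itself targeted.
* **Residence**: the published residence categories cover only 70.1% of
  the cohort; the remainder is treated as unrecorded-scores-as-baseline,
  so the own-home default is 0.799. Laboratory values are drawn uniformly
  within the band implied by their threshold flag. The comorbidity count
  places the configured mass on ≥2 and spreads it as 2 + Poisson(0.7),
  with 0/1 equally likely otherwise — only the ≥2 indicator is scored, so
  the within-band spread is cosmetic.
* **Dependence knobs** (both off by default, since only marginals are
  published): institutionalised patients can be forced into the
  long-term-care residence category, and cognitive impairment can be
  raised among institutionalised patients at a configurable odds ratio
  with the marginal prevalence preserved.
* **Outcomes**: under `mechanism_marginal_rate()` every patient shares a
  piecewise-exponential hazard; under `mechanism_logistic(model)` the named
  model is the true model — 30-day death is Bernoulli with the model's own
  predicted probability, and each patient's later hazard is multiplied by
  $e^{\beta z}$ with $z$ the standardised score ($\beta = 0.6$ by default,
  enough to produce clearly separated risk-group survival curves without
  degenerate high-risk groups).
* **Loss to follow-up** hits a configurable fraction (default 7.6%) at a
  time uniform over the 8-year window; with these defaults about 0.9% of
  patients (0.076 × 365/2922) are unknown at 1 year. One subtlety: the crude rate that excludes patients lost alive
  before the horizon is *not* an unbiased estimate of the latent marginal
  mortality, because patients who die while still under follow-up are
  never excluded — the kept set is death-enriched (about +1.1 percentage
  points at 8 years under these settings). Since the generator's contract
  is that the *observed* rates match the configured targets, the rate
  calibration solves for the piecewise-exponential parameters using the
  analytic expectation of the crude rate under the censoring overlay,
  rather than the latent distribution function.

Generation is vectorised and deterministic given `(config, seed)` via R's
Mersenne-Twister; a 100 000-patient cohort generates in well under a
second.

What passing tests on synthetic cohorts do and do not show: they verify
that the scoring, labelling and metric machinery is correct and that the
generator hits its configured marginals, discrimination ordering and
calibration; they cannot certify the models' real-world performance, since
real cohorts have correlated covariates, non-uniform loss to follow-up and
outcome mechanisms that none of the three models capture exactly.

## Worked example

```{r}
cohort <- generate_cohort(cohort_config(
  n = 344, seed = 1,
  outcome_mechanism = mechanism_logistic("NHFS")))
report <- run_validation(cohort, quiet = TRUE)
report
```

Note that the probabilities entering the calibration test are always the
models' *30-day* risk equations. At the 1-year and 8-year horizons observed
mortality is several times the predicted 30-day risk, so the
Hosmer–Lemeshow test rejects essentially always there — an expected
horizon mismatch, not a bug; at long horizons the informative columns are
discrimination and the risk-group predictive values, and that is how the
long-horizon results should be read.

At n = 344 the confidence intervals are wide and single replicates
fluctuate — with ~20 deaths at 30 days no validation cohort of this size
pins an AUC tightly. The test suite therefore checks distributional properties at
larger n (true-model AUC superiority in the majority of replicates at
n = 5000; Hosmer–Lemeshow type-I error within two binomial standard errors
of 5% at 2000 replicates of n = 1000; marginal recovery within three
binomial standard errors at n = 100 000) rather than asserting any single
cohort's metric values.

## Numerical conventions and degenerate inputs

Internal arithmetic is at full precision; one-decimal half-up rounding is
applied only at presentation. Holt scores are canonicalised to 10 decimals
after summation so mathematically equal sums of two-decimal coefficients
compare equal. Degenerate situations are first-class: a horizon with a
single outcome class skips discrimination and calibration with a logged
warning; an empty high- or low-risk group yields `NA` predictive values; a
cohort with no known status at a horizon is an error; constant predictions
collapse the Hosmer–Lemeshow grouping to one group (the statistic is still
defined). All warnings are collected into the validation report so a run
is auditable.

## Limitations

* Covariates are independent by default; real cohorts are not. The two
  dependence knobs cover the most consequential couplings only.
* The post-30-day hazard is piecewise-exponential with at most one
  score-dependent multiplier — adequate for testing metric machinery, not
  a demographic model of late mortality.
* Recalibration of the models (updating intercepts/slopes on new data) is
  deliberately out of scope; the package validates the models exactly as
  published.
* The original pre-recalibration 2008 NHFS variant is not implemented.
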