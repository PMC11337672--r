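---
title: "Measuring antiseizure-drug use in pregnancy: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring antiseizure-drug use in pregnancy: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupreg)
```

## The problem

Valproate (ATC N03AG01) is a highly teratogenic antiseizure medication, and
regulators have repeatedly tightened its conditions of use in women of
childbearing age — most prominently the EMA pharmacovigilance committee's
October 2014 risk-minimisation measures. Quantifying whether such measures
actually changed prescribing requires a drug-utilisation study on routinely
collected primary-care records: how many pregnancies are exposed, when during
pregnancy exposure occurs, who the exposed women are, and whether the monthly
prescription prevalence bent downward after the intervention.

`dupreg` implements that study design as a reusable pipeline over four
EHR-style tables (women, pregnancy episodes, prescriptions, diagnoses). Real
primary-care databases of this kind are confidential, so the package also
ships a synthetic-EHR generator with recorded ground truth; every stage of
the pipeline is testable by exact recount against the generator's latent
draws.

## Exposure windows

Each pregnancy episode runs from the last menstrual period (LMP) to its end
date and is carved into up to six closed date intervals:

| label   | definition                                   |
|---------|----------------------------------------------|
| PRE90   | `[lmp - 90, lmp - 1]`                        |
| T1      | `[lmp, min(lmp + 97, end)]`                  |
| T2      | `[lmp + 98, min(lmp + 195, end)]` if reached |
| T3      | `[lmp + 196, end]` if reached                |
| POST90  | `[end + 1, end + 90]`                        |
| POST180 | `[end + 91, end + 180]`                      |

Three choices here were genuinely open and are made explicit:

* **Trimester day cut-offs.** No universal day boundary exists; we adopt the
  obstetric convention of first trimester through gestational day 97 (week
  13+6) and second through day 195 (week 27+6). Both are arguments of
  `build_intervals()`.
* **"3 months" as 90 fixed days.** Calendar months vary in length; fixed
  90/180-day margins make every episode's window lattice identical and the
  partition property (`[lmp-90, end+180]` covered with no gaps or overlaps)
  exactly testable.
* **PRE90 anchored at `lmp - 1`.** Anchoring the pre-conception window one
  day before the LMP keeps it disjoint from T1, so no day is double-counted
  between windows.

Only episodes whose onset *and* end fall inside the observation window
(default January 2011 – June 2020) are analysed, and each window is kept only
if it is fully observable in that range. Observability is decided per window:
losing a PRE90 that starts in 2010 does not discard the trimesters of the
same episode, which is why every rate has a label-specific denominator.

## Exposure classification

A window is **prevalent-exposed** when any prescription with the matching
ATC prefix overlaps it by at least one day (`max(starts) <= min(ends)` on
closed ranges). Prefix matching means a subgroup analysis (`N03AG`) and a
substance analysis (`N03AG01`) share one code path.

A window is **incident** (new use) when a matching prescription *starts*
inside it after a washout: no matching prescription active on any day of the
preceding 365 days. Two deliberate strictnesses:

* The washout checks prescription *activity*, not just start dates — a
  prescription issued two years earlier but still active blocks new-user
  status.
* The washout must be verifiable: windows starting less than 365 days after
  the start of observation are flagged washout-ineligible and excluded from
  incidence denominators, because the look-back cannot be seen in the data.

One boundary case is undefined in the narrative study designs this follows:
a prescription initiated in an earlier window of the same pregnancy does not
make a later window incident here — incidence requires the start date inside
the window itself. Both flags are emitted, so a user who prefers a
pregnancy-level new-user definition can derive it from the same status table.

These definitions give two invariants the test suite asserts on arbitrary
inputs: the incident set is a subset of the prevalent set, and lengthening
the washout can only shrink the incident count.

## Rates and confidence intervals

Window-level prevalence and cumulative incidence are binomial proportions
reported per 1000 pregnancies. Interval rates default to the exact
Clopper–Pearson interval via the beta-quantile relation; descriptive
(Table-1-style) percentages default to the Wald interval, floored at 0.
The pairing reflects how such studies conventionally print their results:
exact bounds for the headline per-1000 rates, normal approximation for
descriptive percentages. Both methods are available everywhere through
`ci_method`. The test suite checks the exact bounds against an independent
oracle that inverts the binomial tail probabilities by root-finding, and
checks empirical coverage at n = 300, p = 0.3 over 2000 simulations.

The monthly prevalence series counts, for each calendar month, pregnancies
ongoing during the month (denominator) and those whose prescription overlaps
the *intersection of the gestation and the month* (numerator). Requiring
overlap with the pregnant days of the month — not merely any day of the month
— keeps the series a statement about prescriptions during pregnancy. Months
are true calendar months here; the fixed-90-day convention applies only to
the per-episode window lattice.

## The interrupted time series

Monthly counts `y_t` with denominator `n_t` are modelled by segmented Poisson
regression with log link and offset:

```
log E[y_t] = log n_t + b0 + b1 t + b2 post_t + b3 tpost_t
```

where `post_t` steps to 1 in the first calendar month *after* the
intervention month (default: intervention October 2014, first post month
November 2014) and `tpost_t` counts months since the intervention. The
effect is reported two ways, because "percent monthly decrease" is ambiguous
between them:

* **Slope-based**: `100 * (exp(b3) - 1)`, the change in the month-on-month
  trend, with a Wald CI on the log scale.
* **Counterfactual contrast**: fitted post-period totals against the
  prediction with `b2 = b3 = 0`, i.e. the pre-trend continued; its CI is a
  parametric bootstrap (default 1000 draws) from the multivariate-normal
  coefficient sampling distribution.

Autocorrelation is handled the way applied segmented-regression analyses
usually do: a Ljung–Box portmanteau test on the deviance residuals, with an
optional lag-1 outcome covariate (continuity-corrected log lagged rate) as
the remedy when the diagnostic fires. With a lagged outcome in the model the
counterfactual contrast is computed conditional on the observed lag path;
a fully dynamic counterfactual would require simulating the lag recursion
and is out of scope.

A Gaussian comparator (identity link on the monthly rates) is provided for
model choice by AIC. Its AIC is mapped onto the count scale with the
change-of-variables Jacobian (`+ 2 * sum(log n_t)`); without that correction
the two AICs would live on different data scales and the comparison would be
meaningless. No overdispersion rescaling is applied; the Pearson dispersion
statistic is reported as a diagnostic.

Two exact invariances of this parameterisation are asserted in the tests:
doubling all denominators moves only the intercept (by `-log 2`), and
shifting the calendar origin never changes the slope-based percent effect.

## The synthetic-EHR world

`simulate_cohort()` generates the four tables from a parameterised world
whose defaults are fixed once, up front, to the study conditions the
pipeline is meant to emulate:

* **Pregnancy process.** Eligible women conceive with monthly probability
  0.0014, which together with the gestation mixture keeps roughly 1% of
  women pregnant in any month. Gestation is a two-component mixture —
  early terminations (uniform 6–14 weeks, mass 0.295, matching the abortion
  share of the outcome distribution) and term deliveries (normal around
  39.5 weeks, truncated to 37–42) — reproducing the strongly bimodal
  duration distribution of exposed pregnancies (median near 38 weeks with a
  first quartile near 13).
* **Exposure.** A prescription is active at conception with probability
  0.003, modulated by a log-linear calendar trend with a step and slope
  break at the intervention date (defaults: pre-slope −0.001/month, level
  change log 0.95, slope change log 0.973 ≈ −2.7%/month). Continuation
  probabilities 0.97 / 0.67 / 0.86 through T1 / into T2 / into T3 were
  back-derived from the declining per-window prevalence profile such
  studies report (≈3.1, 2.9, 2.0, 1.7 per 1000 from PRE90 to T3), with a
  post-partum rebound from continuation (0.6) plus restarts (0.2).
  Unexposed pregnancies may initiate in any window with small per-window
  probabilities, giving the incidence machinery something to find.
* **Records.** Coverage periods are emitted as consecutive 90-day
  prescription renewals, so the overlap rule sees realistic date ranges
  whose union equals the latent coverage exactly. Comorbidities are
  independent Bernoulli draws per episode (probabilities concentrated on
  epilepsy and anxiety among the exposed) — independence is a modelling
  choice; real multimorbidity is correlated, but no joint distribution is
  published to calibrate against. Smoking status, which has no column in
  the four-table schema, is represented as status records in the diagnoses
  table (Z72.0 active, Z87.8 history, Z71.6 recorded non-smoker; the
  mapping is configurable), with ~81% of women having no record.
* **Reproducibility.** Each woman has a random substream derived
  deterministically from the master seed, so enlarging the cohort appends
  women without perturbing existing ones, and a fixed seed makes the whole
  pipeline byte-identical across runs.

Every latent draw (per-window exposure flags, initiation dates, comorbidity
draws) is recorded as ground truth, and the test suite recovers it from the
emitted tables *exactly* — not approximately — via the exposure module.

`simulate_monthly_series()` is the generator's counterpart for the ITS: it
draws monthly counts directly from the segmented Poisson model, which is
what parameter-recovery testing needs (estimates averaged over replicates
should sit on the generating coefficients).

What the generator does **not** emulate: realistic demography or fertility
age structure, dose and adherence, correlated comorbidity, per-woman
registration gaps or transfer-out censoring, and seasonality in conception
or prescribing. Passing tests therefore certify the pipeline's logic and
the estimators' calibration under a known world, not the epidemiology of
any real population.

## Problem sizes and numerical choices

The test suite and the acceptance script keep simulations at sizes chosen
to make their target quantities statistically sharp but cheap: cohorts of
1500–6000 women for recount and distribution checks, 96-month series with
1000 ongoing pregnancies per month and 100 replicates for ITS recovery, and
2000 binomial replicates for CI coverage. Exact-recount tests are size-free
(equality either holds or it does not); replicate counts were sized so the
Monte-Carlo error of each checked mean is several times smaller than the
asserted band.

Other numerical details: dates are handled as R `Date` (integer days);
closed intervals throughout; Clopper–Pearson at the 0/n boundaries uses the
conventional 0 and 1; the Wald interval is clamped to [0, 1]; GLM fitting is
standard `stats::glm` IRLS at its default convergence tolerance; bootstrap
draws use `MASS::mvrnorm`. Degenerate inputs fail loudly: zero denominators,
all-zero count series, interventions at the series edge, and episodes
violating `lmp < end` or the 45-week cap are errors, not warnings.

## Limitations

* Cumulative incidence is a proportion of washout-eligible windows, not a
  person-time rate; no survival machinery is involved.
* The ITS evaluates a single intervention; multiple-intervention designs
  (e.g. a later pregnancy-prevention programme) need additional segments.
* Wald intervals on small descriptive counts are anti-conservative; the
  exact method is available but descriptive tables follow the field's
  convention.
* The generator's trend acts on exposure at conception and initiation
  probabilities; it does not separately model discontinuation dynamics over
  calendar time.
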