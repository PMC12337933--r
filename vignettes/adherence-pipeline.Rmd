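---
title: "Adherence and drug-utilization patterns from dispensing records: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adherence and drug-utilization patterns from dispensing records: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxadhere)
```

This vignette documents the models and procedures implemented in
`rxadhere`, the assumptions behind them, the parameters a user can tune,
the design choices made where the methodology was genuinely open, and the
limitations of validating them on synthetic data.

## The estimation problem

Pharmacy dispensing records — one row per dispensing with patient
identifier, date, ATC code and days of supply — are an objective proxy for
medication exposure. For a new user of antihypertensive monotherapy, three
families of questions arise:

1. **How adherent is the patient?** Measured as the proportion of days
   covered (PDC) by dispensed supply, annually and over the whole
   follow-up, and dichotomized at 0.8.
2. **What happens to the regimen?** Patients continue, discontinue, switch
   to another class, or add a second class on top of the first.
3. **Which baseline factors predict these outcomes, and how do the five
   drug classes compare on time to attaining high adherence?**

The package answers all three from the raw dispensing table, with a
new-user (inception) cohort design: only patients observed from their very
first antihypertensive dispensing enter, so "time zero" is
pharmacologically meaningful and prevalent-user bias is avoided.

## Cohort construction

The index date is the first dispensing of one of the five monotherapy
classes (thiazides C03AA; CCBs C08C/C08D/C08E; ACE inhibitors C09A; ARBs
C09C; beta-blockers C07A) inside the study window, with no dispensing of
any of the five classes in the preceding 730 days. Records predating the
study window count as washout evidence: a patient whose earlier exposure
lies before the window start is a prevalent user, not a starter. Two
distinct exposure classes dispensed on the index date mean the start was
not monotherapy; such patients are rejected.

Exclusions remove patients with dispensings suggesting established
cardiovascular disease or secondary hypertension (acute cardiovascular
therapy, chronic heart failure, migraine, adrenal disease,
hyperparathyroidism, thyroid disease) in `[index − 730, index + 90]` days,
and patients younger than 18 at index. The named conditions are mapped to
editable ATC prefix defaults (`default_class_map()`); users with local
coding conventions should review them.

Follow-up ends at the earliest of: study end; 3780 days (ten years); the
first acute-cardiovascular-drug dispensing; the end of supply of the last
initial-class dispensing; and the first change of the initial monotherapy
(another exposure class or an antihypertensive fixed-dose combination).
Ties resolve in that order. "End of supply" — last dispensing date plus
its days of supply — is used rather than the raw dispensing date so that a
patient is not censored in the middle of a dispensed supply; the raw-date
convention can be recovered by setting days of supply to zero-length
intervals upstream, and the choice is isolated in
`determine_followup_end()`.

Baseline covariates are age at index in completed years, banded 18–39 /
40–69 / ≥ 70; sex; nine comorbidity-drug flags (at least one matching
dispensing within the first 180 days from index, closed window); and the
calendar period of the index date with half-open bins [1996, 2000),
[2000, 2010), [2010, 2021) — the printed period labels share endpoints, so
half-open bins are the only consistent reading.

Same-day duplicate dispensings of one class are reduced to the one with
maximum days of supply by the coverage union itself; how the source study
handled them is not documented, and this is the simplest convention that
keeps coverage monotone.

## Coverage and PDC

All day arithmetic is relative to the index date (day 0) with half-open
supply intervals `[dispense_day, dispense_day + days_supply)`. Two overlap
policies are implemented and tested:

* **carryover** (default): an early refill starts when the previous supply
  ends, the usual PDC convention for chronic therapy — patients stockpile;
* **truncate**: plain set-union of intervals; overlapping days count once.

Annual PDC for year *k* is the covered-day count in
`[360(k−1), 360k)` divided by a fixed 360-day denominator. A year window
that is not fully inside follow-up is flagged not evaluable (`NA`) rather
than reported as a deflated rate; the year-*k* estimate is thereby
restricted to patients persisting more than 360·*k* days. Overall PDC
divides covered days in `[0, followup_end)` by the follow-up length. Both
are capped at 1 (no credit for oversupply), and high adherence is
PDC ≥ 0.8, cutoff inclusive. Whether a covered day is counted on the
follow-up end day itself is governed by the half-open convention: it is
not.

## Pattern classification

Discontinuation is a refill gap of the initial class exceeding 180 days,
dated at the end of supply. Two boundary decisions deserve note:

* The gap must be *fully observable*: a supply-end within 180 days of the
  censoring date is not a discontinuation — otherwise every censored
  continuer would be flagged at their final supply-end. Concretely, the
  event at supply-end `e` requires `e + 180 < followup_end`.
* A dispensing exactly 180 days after supply-end closes the gap (the rule
  is "more than 180 days").

A switch is the first other-class or fixed-dose-combination dispensing in
`(disc_day, disc_day + 180]`; an add-on is the first other-class/FDC
dispensing on a day strictly inside initial-class coverage and before any
discontinuation. Under the half-open convention a dispensing on the exact
end-of-supply day is outside coverage, so it can never be an add-on; it is
also not yet "after discontinuation", so it is neither event. One patient
may have both an add-on (before stopping) and a switch (after), so the
non-continuation categories are not mutually exclusive and class-level
percentages may sum to more than 100.

Patterns are classified over an observation horizon of
`min(study_end − index, 3780, first acute-CV day)` days rather than the
PDC follow-up end: the cohort's follow-up rule censors at regimen change,
under which a switch could never be observed inside follow-up. The
descriptive pattern analysis is restricted to patients on the original
monotherapy for more than 360 days, mirroring the cohort selection used
for the corresponding objective.

## Risk clustering

All risk factors are unordered categoricals, so the Gower dissimilarity
with equal weights reduces to the proportion of mismatching variables
(binary variables treated symmetrically; asymmetric-binary handling is
deliberately not used, since "no comorbidity drug" is as informative as
"comorbidity drug"). Distances lie in [0, 1] and form a metric.

`pam_fit()` performs k-medoids clustering. When the number of candidate
medoid sets `choose(n, k)` is at most `exact_limit` (default 5000) the
global optimum is found by exhaustive enumeration; otherwise BUILD
initialisation followed by steepest-descent SWAP is used, with ties broken
by the lowest row index so results are deterministic. The enumeration
guarantee matters: BUILD+SWAP is a local search and can, on a few percent
of small random instances, terminate in a local optimum. The number of
clusters is selected by the average silhouette width over `k = 2..10`,
with the standard `s(i) = 0` convention for singleton clusters. Above a
configurable size threshold (default 10 000 in `cluster_patients()`, 2000
in the pipeline), the full distance matrix is not materialised: clustering
runs on a seeded subsample and remaining patients are assigned to the
nearest medoid by direct Gower distance — a subsample-and-assign strategy
in the CLARA tradition. The seed controls only the subsample draw; the
core algorithm is deterministic.

Whether adherence is itself a clustering variable (for the pattern
outcomes) or only a model covariate is ambiguous in the source design;
`feature_table(cohort, adherence = ...)` supports both modes.

## Prediction models

Associations among the categorical predictors are screened with Cramér's V
(uncorrected χ², no bias correction) and multicollinearity with VIFs
computed on the dummy design (`1/(1 − R²_j)`; exact collinearity reported
as infinite). Dummy encoding drops the most frequent level of each
variable as reference. Variables with a single observed level — which can
arise inside small clusters — are dropped before fitting, as they carry no
information and break estimation.

`cv_penalized_fit()` draws a stratified 70:30 train/test split, assigns
10-fold CV folds (both governed by one recorded seed), and fits ridge
(α = 0), LASSO (α = 1) or elastic net (α = 0.5; the mixing value is a
package default, configurable) over glmnet's 100-value log-spaced lambda
grid. Columns are standardized internally by glmnet and coefficients
reported on the original indicator scale. The three penalties are compared
by RMSE and R² between predicted probabilities and the 0/1 outcome on the
held-out split — with both metrics computed on the same held-out outcomes
they are concordant by construction, but the comparison reports
discordance rather than silently preferring one metric if users supply
metrics computed differently. Exact ties break by higher AUC. Fold-level
AUCs at the chosen lambda are reported alongside the held-out AUC, since
either could be meant by a "cross-validated AUC".

**Choosing lambda.** Two standard rules are exposed:

* `"1se"` — the largest lambda within one standard error of the minimum CV
  deviance. This is the default in `cv_penalized_fit()` because the
  package uses LASSO primarily for *variable selection*, and the 1-SE rule
  is the standard parsimony choice: with planted effects of |log-odds| 0.7
  among six nulls it retains every true variable and essentially no nulls.
* `"min"` — the deviance-minimising lambda. This is the default for the
  *pipeline's* final-model stage, where effect sizes are realistic (0.3–0.5
  on the log-odds scale, further diluted by utilization-pattern
  heterogeneity): there the CV deviance curve is flat within one fold-SE
  and the 1-SE rule collapses to the intercept-only model, while the
  minimum rule recovers the informative variables. The subsequent
  unpenalized refit with Wald inference guards against the minimum rule's
  tendency to over-select.

The final logistic model applies the group-survival rule: a source
variable enters iff at least one of its dummies has a nonzero LASSO
coefficient at the chosen lambda, and then the whole variable (all levels)
is refit without penalty. Reported diagnostics: odds ratios with 95% Wald
intervals; AUC, sensitivity and specificity on the held-out split at the
0.5 probability cutoff (no cutoff rule is given in the source design; 0.5
is the neutral default and configurable); the Hosmer–Lemeshow test on the
training fit with 10 risk groups (ties kept together, groups with zero
expected count merged, χ² with groups − 2 df); and Nagelkerke R²
(Cox–Snell rescaled by its maximum). A sensitivity mode
(`plain_logistic()`) skips LASSO entirely and fits all multi-level
variables, mirroring the unpenalized re-analysis a careful study would
run.

## Survival analysis of time to high adherence

The source design defines follow-up in 180-day half-year periods but never
states how "transition to high adherence" was operationalized. The
package's rule — documented as its own and fully configurable — is: PDC is
evaluated on consecutive 180-day windows from index, and the event occurs
at the end of the first fully observed window with PDC ≥ 0.8; otherwise
the patient is censored at `min(followup_end, 1080)` days. The three-year
analysis is run in patients whose drug records of any kind span more than
1080 days.

Kaplan–Meier curves estimate the probability of *remaining in low
adherence* (non-decreasing hazard of the event pulls the curve down over
time). Exposure groups are compared with Cox models, reference
beta-blockers, Efron tie handling. Confounding by baseline covariates is
addressed with stabilized inverse-probability-of-treatment weights from a
multinomial-logistic propensity model of the five classes on sex, age
band, the nine comorbidity flags and calendar period; weights are
truncated at their 1st/99th percentiles and near-zero fitted probabilities
trigger a non-overlap warning. Weighted fits use robust sandwich
variances. Balance is reported as the maximum pairwise standardized mean
difference per covariate dummy, weighted and unweighted.

Time-dependent exposure effects use the counting-process expansion over
episodes 0–180, 180–540 and 540–1080 days (cutpoints configurable), with
one explicit exposure-by-episode indicator per class and interval — the
first-interval coefficient is what "effect at baseline" refers to here.

Model performance: cumulative/dynamic time-dependent AUC at 1080 days with
inverse-probability-of-censoring weights from the Kaplan–Meier censoring
estimate (patients censored event-free at exactly the horizon are known
event-free and count as controls); sensitivity and specificity at the
Youden-optimal threshold of the 1080-day risk score; Nagelkerke R² from
the partial-likelihood ratio (with n the number of subjects); and
Harrell's C over usable pairs.

## The synthetic generator

No dispensing database ships with the package, so `simulate_population()`
generates one with planted ground truth. Its defaults are the package's
study conditions, chosen once to be realistic for chronic antihypertensive
therapy, and every analysis stage is validated against the labels it
plants.

Per patient: covariates are drawn first (age band 25/55/20%
young/middle/older, 48% male, comorbidity prevalences between 2% and 12%,
index dates uniform over 1996–2017 so everyone has at least three years of
observable history). High adherence is then drawn from a logistic model on
the covariates; the default log-odds (intercept 1.1; middle age 0.35;
older 0.5; diabetes drugs 0.4; asthma/COPD drugs 0.3; psycholeptics −0.4;
calendar periods 0.3/0.45; sex 0) reproduce the direction and rough
magnitude of effects reported for this population, and yield a first-year
high-adherence rate near 85%. The planted flag sets the refill-delay
factor: high-adherence patients refill on time (delay 1.0), low-adherence
patients late (delay 1.45, PDC ≈ 0.69), and each gap is
`days_supply × delay × U(1 − jitter, 1 + jitter)` with jitter 0.1 (0 gives
deterministic schedules). These two delay levels separate cleanly at the
0.8 cutoff, which is what makes covariate-effect recovery testable: the
observed year-1 flag equals the planted label almost surely.

Archetypes (defaults 30% continuer, 40% discontinuer, 12% switcher, 18%
adder, matching the qualitative ordering reported for new users) drive the
event structure: continuers refill to the horizon; discontinuers stop
after a Geometric(0.3) number of refills; switchers additionally start a
different class 1–180 days after their supply ends; adders start a second
class on a day drawn uniformly from covered days ≥ 30. Planted events are
capped so they remain observable inside the horizon (a discontinuation
needs 181 further days, a switch at most 180 more). An optional
`exposure_confounding` parameter tilts the class draw by age and diabetes
so that IPW analyses can be exercised under known confounding. All days
are integers; fixed seed gives byte-identical output.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: dose titration and pill splitting, irregular
days-supply values, pharmacy switching and record linkage noise, seasonal
refill behaviour, mortality and emigration (censoring is purely
administrative), secular prescribing trends beyond the calendar-period
covariate, and within-class heterogeneity between individual drugs. The
oracle-equivalence tests establish that the implementation computes its
definitions exactly; the recovery tests establish statistical sanity at
realistic effect sizes, not real-world validity.

## Numerical conventions and degenerate inputs

* Day 0 is the index date; all intervals are half-open; PDC denominators
  are exact day counts.
* Empty dispensing lists give empty timelines and PDC 0; non-positive
  days-supply is an error.
* A constant feature table yields an all-zero Gower matrix with a warning;
  `k = n` medoids cost 0; `k > n` is an error.
* Single-class outcomes are an error in penalized fits; if no variable
  survives selection the final model is intercept-only with a warning.
* Exact collinearity reports infinite VIF rather than failing.
* Hosmer–Lemeshow merges groups with zero expected events and keeps
  probability ties in one group.
* Cox fits with no events are an error; separation is surfaced through the
  survival package's warnings.
* Weight truncation counts are reported; `mean(weights) ≈ 1` is a checked
  invariant, not an enforced normalisation.

## Problem sizes used in validation

The test suite and the acceptance script validate at sizes chosen to make
the statistical properties sharp on one CPU: 1000 random histories for the
coverage and pattern oracles; 50 random matrices for exhaustive PAM; 400
patients × 10 seeds per planted cluster count; n = 5000 × 20 seeds for
LASSO selection recovery; n = 5000 for weight calibration and balance;
n = 2000 × 50 seeds for the crude-versus-IPW contrast (true HR 2.0);
n = 1500 × 20 seeds for the time-dependent sign recovery; and a 5000-patient
end-to-end pipeline run. The pipeline itself has no size limit beyond
memory; clustering switches to subsample-and-assign above the configured
threshold.

## Known limitations

* The pattern classifier reports only the first switch and first add-on;
  multi-switch trajectories are out of scope.
* PDC is class-level, not dose-level: a patient covered by any dispensing
  of the index class counts as covered, with no DDD adjustment, and
  combined coverage across classes is not computed.
* The event rule for "attaining high adherence" is one reasonable
  operationalization; alternatives (rolling windows, shorter periods)
  change absolute rates, though comparative contrasts are less sensitive.
* IPW balances measured covariates only; the synthetic confounding tests
  cannot speak to unmeasured confounding.
* Silhouette-based selection of k inherits the known bias of silhouettes
  toward well-separated spherical-ish structure; on weakly structured
  risk-factor data the selected k is descriptive, not inferential.
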