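---
title: "Measuring the economic burden induced by cancer screening from claims data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the economic burden induced by cancer screening from claims data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Population-level cancer screening in low-income regions detects many
asymptomatic cancers early, and those cancers are then treated earlier and
in greater numbers than they would have been without screening. When the
screening program funds only the screening itself, the treatment bill lands
on patient households and on the local public insurer. `screenburden`
quantifies that burden from insurance-claims-style records of a two-arm
screening trial: per-case costs from the patient and societal perspectives,
counts of households pushed into catastrophic health expenditure (CHE), and
arm-level total-cost comparisons.

The package is organized as a pipeline over four linked tables —
participants, verified cancer cases, hospitalization episodes, and itemized
expense line items — with an analysis workflow under `analysis/` that runs
the steps in order on a synthetic claims database.

## Case verification

A participant's claims constitute a treated upper-gastrointestinal cancer
case when either criterion holds:

1. some hospitalization's discharge diagnosis code starts with an upper
   G.I. ICD-10 block — C15 (esophagus), C16 (stomach), D00 (carcinoma in
   situ), or K22 (other esophageal disease, covering precancerous
   lesions); or
2. some expense line item records cancer-directed therapy (surgery,
   radiation, or chemotherapy medication).

Matching is at the 3-character block level ("C15.3" matches "C15") because
insurers code at variable depth. Whether the precancerous blocks D00/K22
alone qualify a case for cost analysis is a genuine judgement call; the
package treats them as qualifying by default and exposes `code_prefixes` to
tighten this. Verification is monotone: adding episodes can only turn a
non-case into a case, never the reverse.

## Harmonizing the two arms

In community-based cluster-randomized trials enrollment is staggered:
screening villages enroll first, so by any fixed calendar date the
screening arm has accrued cases for longer than the control arm, and its
cases have had longer to generate claims. Two constructions remove this
asymmetry.

**Uniform follow-up.** The harmonized ("perfect") cohort keeps only cases
diagnosed within $U$ days of their own enrollment, where $U$ is the
shortest follow-up among all verified cases. The boundary is included:
diagnosis at exactly day $U$ qualifies. `uniform_followup()` offers two
definitions of a case's follow-up. The `"survival"` basis uses the
participant's own end of follow-up (death or administrative censoring),
which is the literal record; but a single early death then collapses $U$
to a few hundred days and empties the later-enrolled arm — a pathology of
the definition, not of the data. The `"accrual"` basis measures enrollment
to the administrative censoring date, which is the quantity the
construction is meant to equalize (every participant's *opportunity* to be
diagnosed), so the minimum reflects enrollment staggering only. The
pipeline uses the accrual basis; the survival basis remains available.

**Standard observation window.** Treatment starts at the first
hospitalization with a qualifying discharge diagnosis at a secondary
(county) or tertiary (city and above) facility; ties on admission date go
to the earlier discharge, then record order. The average cost per patient
under observation in month $m$ after that start is

$$\bar c_m = \frac{\text{total cost booked in month } m}
                  {\text{patients under observation in month } m},$$

with months as fixed 30-day bins from the first admission (calendar months
would make bin 1 depend on the admission's day-of-month), an episode's full
cost assigned to the bin of its admission date (no proration — the claims
carry no within-stay cost schedule), and "under observation" meaning alive
and uncensored at the bin start. A month with a zero denominator reports an
average of zero. The curve is L-shaped: treatment cost concentrates in the
first months and decays to near zero by a year. `select_window()` picks
the smallest $m$ after which every average falls below 5% of the month-1
average; the headline analysis fixes the window at 12 months, which that
rule comfortably supports on the default synthetic data (extinction at 3-5
months).

## Cost valuation

All claims amounts are nominal CNY of their service year. Three adjustments
express them as base-year (2018) real USD:

$$c_{\text{real}} = c_{\text{nominal}}
  \times (1+r)^{2018-y} \times \frac{\text{CPI}_{2018}}{\text{CPI}_y}
  \div \text{PPP},$$

with discount rate $r = 3\%$/year compounded on whole-year differences
(past costs are annualized forward to the base year), a medical-care CPI
series normalized to 2018 = 1, and the 2018 purchasing-power-parity rate
of 3.55 CNY per USD. Setting $r=0$, a flat CPI, and PPP 1 reduces every
output to nominal CNY sums, which the tests exploit as a degenerate-
parameter check.

**Time cost** follows the human-capital approach: each inpatient day is
valued at the rural annual net income (ANI) per capita divided by 365, and
doubled because a hospitalized patient in this setting is accompanied by
one caregiver who also forgoes income:

$$\text{time cost} = \text{OLS} \times \frac{\text{ANI}}{365} \times 2,$$

where OLS is the case's overall length of stay across in-window episodes.
The ANI default (12,719 CNY/year, the 2017 statistic for rural Henan) and
the CPI series are user-supplied parameters with documented stand-in
defaults: the source statistics behind the original analysis are not
printed anywhere recoverable. **Treatment cost** is hospitalization cost
plus time cost — an exact identity maintained per case, not a rounded
report-level sum. **Out-of-pocket cost** is the adjusted sum of the
claims' out-of-pocket fields, and can never exceed hospitalization cost.

**Catastrophic health expenditure** (WHO definition) is out-of-pocket
spending strictly exceeding 40% of the household's capacity to pay,
proxied by the county's rural per-capita disposable income (10,906 CNY =
3,072 USD at PPP). "Exceeding" is read strictly: spending exactly at the
threshold is not catastrophic. The comparison always happens within one
currency.

Skewed cost distributions are summarized as mean with lower and upper
quartiles, using linear-interpolation quantiles (`stats::quantile`
type 7); the convention is configurable because no single quartile
definition is canonical. Report percentages round half away from zero.

## Statistical comparisons

Baseline and selection-bias tables use Pearson's $\chi^2$ test without
continuity correction for categorical covariates and the Wilcoxon
rank-sum test for continuous ones, both two-sided. When any expected cell
count falls below 5 the $\chi^2$ approximation is unreliable and the table
switches to Fisher's exact test — with the sparse site-distribution tables
typical of these cohorts, that fallback is what reproduces the published
style of p-values. Univariate logistic regressions on CHE status (the
default outcome; "impact factors of treatment costs" admits several
operationalizations and CHE is the one with a clear policy reading) report
Wald 95% intervals; perfect separation is flagged and the estimate
suppressed rather than reported at an absurd magnitude. No
multiple-testing correction is applied anywhere — these tables are
descriptive screens, reported as raw p-values.

## What the synthetic generator emulates

`claims_generator_config()` defaults encode the study conditions: two arms
of 17,000 participants aged 45-69; screening-arm enrollment 2012-2013,
control 2013-2016; administrative censoring at 2018-12-31; esophageal
cancer incidence 25.58 per 100,000 person-years against 12.45 for the
gastric sites combined (split 6.0 cardial / 6.35 non-cardial, with a
trace duodenal rate). Screening multiplies case occurrence by 2.5 — the
prevalence harvest of endoscopy — and makes 80% of screening-arm cases
screen-detected: diagnosed within ~4 months of enrollment and drawn from
an early-stage-heavy distribution (78% stage 0-I), while clinical cases in
both arms are late-stage-heavy (45% stage IV). Therapy follows stage;
hospitalization counts (1 + Poisson, stage-dependent) and lognormal
lengths of stay are calibrated to the published medians (1 vs 2 episodes,
21 vs 39 days); episode costs are lognormal per therapy and expense
classification, decaying geometrically with a 3-month half-life so the
monthly curve is L-shaped and extinct within a year; reimbursement is a
Beta draw around 50%; stage-dependent death hazards truncate follow-up.
The nine expense classifications (bed, nursing, diagnostics, imaging,
laboratory, surgery, radiation, chemotherapy medication, other medication)
are a configurable stand-in with the correct cardinality — the insurer's
own labels are not public.

Features of real claims the generator does **not** emulate: village-level
cluster correlation, screening test characteristics (every screen-detected
case simply exists), record-linkage noise, transfers between facilities,
within-stay cost schedules (each line item is dated at admission), and the
much higher incidence a 45-69-year-old high-risk cohort shows relative to
the all-ages county rates used as inputs — so synthetic cohorts are
several-fold smaller than the study's, and arm-level ratios on synthetic
data are correspondingly noisier and larger (the screening-to-control case
imbalance is starker at low control counts). Passing tests therefore
demonstrate the correctness of the accounting, harmonization, and
reporting machinery under the stated conditions, not reproduction of the
study's empirical magnitudes from raw data.

## Numerical and design choices

- Dates are ISO-8601; intervals are closed on both ends and measured in
  whole days. Record identity is an opaque `participant_id`; fuzzy
  identity matching is out of scope.
- The out-of-pocket accounting identity (out-of-pocket = total −
  reimbursed) is enforced at read time within 0.01 CNY.
- Internal arithmetic keeps full precision; rounding (integer USD,
  two-decimal ratios, integer percentages) happens only at the reporting
  surface.
- Conservation identities are structural, not approximate: included plus
  excluded cases partition the verified set; the monthly curve's binned
  totals sum to the window-assigned episode costs; each accumulated curve
  ends exactly at its stratum's total treatment cost; per-classification
  means sum to the arm's mean hospitalization cost.
- Duodenal cancer reports under an `"other"` stratum, outside the two
  headline site groups (esophageal; cardial plus non-cardial gastric).
- Problem sizes in the test suite are scaled to a few hundred to a few
  thousand participants with boosted incidence, which gives hundreds of
  cases in seconds while exercising every code path; the analysis scripts
  run the full 17,000-per-arm conditions.

## Known limitations

Costs are inpatient-only plus hospitalization time cost: outpatient care,
travel, and productivity losses beyond the inpatient stay are excluded by
design, as is any effectiveness or cost-effectiveness analysis. The
12-month window approximates lifetime treatment cost, which the L-shaped
cost flow justifies but does not prove for other settings. Selection-bias
checks on synthetic data typically *do* show imbalance in detection mode
between included and excluded cases (exclusion operates on diagnosis
delay, which the generator ties to detection mode) — a reminder that the
generator is a testbed, not a replica of any real cohort.
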