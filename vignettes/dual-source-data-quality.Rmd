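---
title: "Auditing EHR data quality against paper charts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing EHR data quality against paper charts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehrdqa)
```

## The problem

In many HIV care programmes, clinical data are written into a paper chart at
the point of care and later transcribed into an electronic health record
(EHR). The EHR's value — for patient care, programme monitoring and
surveillance — depends on how faithfully it mirrors the chart. `ehrdqa`
implements a facility-level audit of that fidelity: trained abstractors
record 28 key variables per patient from *both* sources (demographics,
facility identifiers, HIV-care milestone dates, up to three antiretroviral
regimen lines, the last three drug pickups, and the last three viral-load
results), and the package scores completeness, matching, and concordance of
the resulting record pairs, then relates data quality to facility
characteristics and to the presence of clinical-decision-support alerts.

The audit follows a lot-quality-assurance-sampling (LQAS) design: 48--76
charts are sampled per facility depending on patient volume
(`lqas_sample_size()`), and a metric is classified *high quality* when it
reaches 85% (`>=`, one configurable threshold used everywhere).

## Metrics

For each variable $v$ and source $s$,

* **completeness** $= \dfrac{\#\{\text{records with } v \text{ non-missing in } s\}}{\#\text{records}}$,
* **matching** $= \dfrac{\#\{\text{records where standardized values agree}\}}{\#\{\text{records with } v \text{ non-missing in both sources}\}}$,
* **concordance score** (per record) $=$ the number of 15 designated
  variables that either match or are missing in *both* sources (a
  both-missing field counts as agreement), an integer 0--15.

A value is *missing* when the field is blank, carries a not-available code,
or — for dates — fails to parse, equals a sentinel placeholder (by default
1980-01-01, a well-known habit when the true date is unknown), lies after
the chart-abstraction date, or (for HIV-care dates) precedes the start of
HIV treatment in the country. The paper that motivated this design states
the rule but not the cutoffs; the defaults (abstraction 2018-12-01, HIV
epoch 2002-01-01, date of birth window from 1900) are configurable in
`missingness_config()`. Which variables the epoch rule covers is likewise a
design choice: we apply it to all HIV-care event dates (first positive
test, enrollment, ART start, regimen starts, pickups, viral-load draws) but
not to the date of birth or the last-visit date.

*Standardization before matching.* Drug regimens are canonicalized
(`canonicalize_regimen()`): components split on `+`, commas or "and", names
case-folded and accent-stripped, doses normalized, the multiset sorted — so
`"Tenofovir (300) + Lamivudine (300) and Efavirenz (600)"` equals the same
combination written with different separators or order. No spelling
correction is attempted (a synonym map can be supplied). Viral loads match
within 1 copy/mL (`vl_values_match()`), absorbing decimal-precision
differences such as 20.6 vs 20. Dates must agree exactly.

*Viral-load alignment.* Each source holds up to three (value, date)
entries, newest first. Position-wise comparison penalises an EHR that is
simply one result behind, so `align_vl()` pairs entries on exact calendar
date; unpaired entries count as missing in the other source. The
concordance score takes the most recent *aligned* pair by default
(`vl = "aligned"`); the positional variant is available because the
original audit is ambiguous on this point. The lenient "at least one viral
load" flag (`at_least_one_vl()`) asks only whether the newest EHR value
matches any of the three paper values, without date agreement — the
quoted definition mentions none, and we flag this choice for users.

## Association analyses

Concordance is correlated with facility survey covariates (EHR
availability/uptime on a 1--5 Likert scale, a 0--4 technology-experience
score, mean years of EHR use) at *record* level — each audited chart is one
observation with its facility's covariate attached — using Pearson
correlation with a Fisher-z interval and Bonferroni adjustment across the
covariates tested together (`concordance_covariate_correlation()`).
Record-level analysis mirrors the original audit (its degrees of freedom
imply record-level n); facility-level aggregation can be done by summarising
first.

The alert effect is a 2x2 contingency analysis (`alert_effect_table()`):
records from the post-intervention period (filtered on the last-visit
date), rows alert vs no-alert facilities (alert tier >= 2, i.e. the
missing-viral-load alert), columns matched vs unmatched. A record counts as
*matched* for the viral-load family when the EHR holds an entry with the
same date as the chart's most recent post-cutoff result and a value within
1 copy/mL; for the pickup family when some EHR pickup slot carries the same
date and canonically equal drugs as the chart's most recent pickup. The
chi-square statistic is computed from the classical closed form with the
Yates continuity correction by default (both variants are reported; on the
audit's published pickup table the corrected statistic is 67.5, the
uncorrected 68.4, and the published value matches the corrected one). The
effect size is $\phi = \sqrt{\chi^2_{\text{uncorrected}}/N}$, with a seeded
nonparametric bootstrap CI (2000 multinomial resamples, percentile
interval) by default — the CI method is not specified in the source audit,
and a Fisher-z alternative is provided.

## The synthetic-data generator

No patient records ship with the package; `simulate_dqa()` generates
study-shaped datasets so that every pipeline stage is testable and
calibratable. The default `simulation_config()` *is* the audited study's
condition set: 50 facilities, half intervention, 11 of 25 intervention
facilities with the missing-viral-load alert, 48--76 charts per facility
summing to exactly 3467 records (hence 3467 x 28 x 2 = 194,152 data cells
and 69.34 records per facility), abstraction on 2018-12-01 with the alerts
live from 2018-07-01.

Error processes, applied to ground truth drawn from simple plausible
distributions (dates uniform in windows, viral loads log-uniform over
20--10^6 copies/mL, regimens from a six-item formulary):

* per-variable fill probabilities and, for "direct" variables,
  EHR-vs-paper match probabilities (`study_variable_profile()`), set to the
  completeness and matching levels the original audit reported —
  demographics near-perfect, milestone dates complete but mismatching
  6--40% of the time, second/third-line regimens rare;
* sentinel rendering: a missing date is written as 1980-01-01 rather than
  left blank with probability 0.3 (a modelling choice; either way the cell
  is missing under the rules);
* transcribed dates are offset, within 30 days with probability 0.36 for
  one-off dates and 0.12 for repeated dates (the audit's observed error
  pattern), reflected backwards if they would cross the abstraction date
  so an error never masquerades as impossible-date missingness;
* *staleness* for repeated fields: the EHR's last-visit date and pickup
  slots are current with probability `last_visit_match_prob` /
  `pickup_recent_match_prob` and otherwise lag one encounter behind;
* *viral-load lag*: a post-cutoff most-recent result reaches the EHR with
  probability `vl_recent_match_prob` (default 0.119), multiplied by
  `alert_effect` (default 2.24) at alert facilities — the mechanism the
  missing-VL alert targets; older entries are present with probability
  0.72 and carry their own date/value transcription errors;
* dialect variants that standardization must absorb: split regimen
  rendering ("A + B and C") and paper-side decimal viral loads;
* facility effects: record-level EHR error and missingness probabilities
  are scaled by $2\,\mathrm{plogis}(-(0.3(\text{avail}-3) -
  0.2(\text{tech}-2)))$, giving the availability correlation a known
  positive and the technology-experience correlation a known negative
  sign; the covariate distributions are symmetric, so the multiplier has
  mean exactly 1 and marginal rates are preserved.

Every observed-vs-truth discrepancy carries an error label in the
ground-truth sidecar (`missing`, `sentinel`, `transcribed`, `lagged`,
`split`, `precision`).

Under these defaults the simulated mean concordance comes out near 10
of 15 — the value implied analytically by the configured completeness and
matching rates — and the alert-effect percentages sit near 27% vs 12%.
What the generator does *not* model: visit scheduling, disease
progression, correlated missingness within a chart, abstractor-specific
behaviour, or more than three entries per repeated family. Tests passing
on synthetic data therefore validate the *metrics and statistics*, not any
claim about real facilities.

## Numerical and design choices

* The 85% threshold is applied with `>=` in both the completeness and the
  matching rule.
* "Within 1 month / 3 months" date-error buckets use 30/90 days; month
  length is not otherwise defined.
* Matching with a zero denominator is reported as `NA` ("not applicable"),
  never as 0.
* Viral loads are compared on raw numeric values with absolute tolerance
  1; no prior rounding.
* Duplicate same-source viral-load dates are a data anomaly: they pair
  deterministically in position order with a warning.
* Records whose viral-load series has no valid-dated entry on either side
  fall back to positional slot-1 values in the aligned concordance.
* The LQAS volume-to-sample-size step is a linear interpolation from 48
  charts at volume 500 to 76 at volume 3000, clamped to
  `[48, min(volume, 76)]`; the protocol's exact published table can be
  substituted via the function's arguments.
* Type-I calibration of the alert-effect analysis is assessed on the
  *uncorrected* chi-square: the Yates correction is deliberately
  conservative and would not calibrate to the nominal 5%.
* Degenerate inputs (zero-variance covariates, zero table marginals on
  noiseless data) surface as "not estimable" notes in the pipeline report
  rather than aborting the run.

## Problem sizes used in the test suite

The shipped tests run the full study shape (3467 records, 50 facilities)
for parameter recovery and effect detection, 500 replicates of a 20-facility
/ 1200-record configuration for the null calibration of the alert-effect
test, and small constructed fixtures (<= 20 records) for the brute-force
oracle comparisons — sizes chosen so each property is tested at the scale
where its guarantee is stated while the whole suite completes in minutes.

## Limitations

Beyond the generator's simplifications listed above: matching is rule-based
and exact (no fuzzy matching or probabilistic record linkage); the
alert-effect analysis treats alert presence as a facility attribute and
does not model the alert software; clustered standard errors and
mixed-effects models are out of scope (the record-level correlations
inherit the original audit's design, including its optimism about
within-facility dependence); and the concordance score weights all 15
variables equally regardless of clinical importance.
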