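---
title: "Screening for impending brain death: rule, evaluation and simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for impending brain death: rule, evaluation and simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(bdscreen)
```

## The screening rule

The engine scans each patient's charted observations on a fixed 12-hour
cycle. At a tick $t$ the patient screens positive when both hold:

* **Coma**: the freshest RASS is $-4$ or $-5$, *or* the freshest GCS lies in
  $[3, 6]$. The two scales are treated as independent observations; no
  conversion between them is attempted.
* **Bilaterally absent pupillary light reflexes**: both eyes carry a fresh,
  explicit *absent* finding. `not_assessable` and undocumented pupils fail
  the criterion — an alerting system must not fire on missing data.

Positivity is therefore monotone in sedation depth given the pupils, a
property the test suite checks directly.

### Freshness (staleness windows)

Real flowsheets are charted irregularly, so the engine reads
*last-known-fresh* values: an observation counts at $t$ only if charted at or
before $t$ and no older than a per-kind staleness bound. Defaults: 12 h (one
screening cycle) for RASS, GCS and the pupil findings — critical-care
monitoring guidance has these charted at least once per shift — and 24 h for
pressures, sodium and ventilation status, which are charted or drawn less
often. Resuscitation events never expire: the corresponding flag means "any
CPR at or before $t$, including a pre-admission marker charted at
admission". The bounds are configurable (`engine_config()`); whether a
deployed system should insist on same-cycle charting or accept last-known
values of any age is genuinely open, and exposing the window makes the choice
explicit and testable.

### Tick schedule

Ticks fall on fixed wall-clock anchors (06:00 and 18:00 by default), not at
admission-relative offsets — screening services run on hospital clocks, and
an "06:00 day-4 alert" is the natural unit of such a system. Ticks run
strictly after admission and stop at discharge, or at the brain-death
determination time when the outcome is confirmed, so post-mortem charting
can never generate alerts.

### Notifications

Every positive tick emits one notification with a demographic snapshot and
six optional clinical flags computed from events at or before the tick only
(no lookahead — a property test perturbs future events and asserts tick
results are unchanged):

| flag | rule |
|---|---|
| ventilated, no spontaneous breathing | freshest `VENT_CONTROLLED` true **and** freshest `SPONT_BREATHING` false |
| intracranial pressure | freshest ICP strictly $> 50$ mmHg |
| cerebral perfusion pressure | freshest CPP strictly $< 20$ mmHg |
| sodium, absolute | freshest sodium strictly $> 160$ mmol/L |
| sodium, 24-h change | $\max - \min > 10$ mmol/L over $(t-24\,\mathrm{h}, t]$, requiring $\ge 2$ values |
| resuscitation | any CPR event at or before $t$ |

Boundary strictness follows the wording of the thresholds ("above 50" means
$>50$, etc.), so a value sitting exactly on a threshold does not flag. The
24-h sodium change is read as the range (max − min) of the window: the
pairing of values is otherwise unspecified, and the range is the most
sensitive deterministic reading; it needs at least two values, since a single
measurement carries no change information.

A patient is *screen-positive* for evaluation purposes when they have at
least one notification during the admission; *repeat-detected* when they have
more than one. A repeat is any notification after the patient's first — no
episode concept is imposed. Duplicate patient identifiers are rejected
(overlapping admission windows are an error; the evaluation unit is the
patient, so even disjoint re-admissions under one id are refused rather than
silently merged).

## Accuracy evaluation

Patient-level classification against the confirmed brain-death outcome gives
the confusion matrix; sensitivity, specificity, predictive values and
accuracy follow with their denominators. Interval choices:

* **Clopper–Pearson (exact)**, via Beta quantiles, is the default. It is
  conservative, behaves sensibly at the boundary (for $x=n$ the lower bound
  is $(\alpha/2)^{1/n}$ — with 8/8 that is 63.06%), and is what diagnostic
  calculators commonly print.
* **Wilson score** intervals are provided as the alternative; both are
  cross-checked in the tests against independent implementations
  (`binom.test`, `prop.test(correct = FALSE)`) and against exact coverage
  computed by binomial enumeration.
* **Predictive values** are prevalence-dependent post-test probabilities, so
  they get delta-method intervals on the logit scale built from sensitivity,
  specificity and prevalence (the standard predictive-value method):
  $\mathrm{Var}(\mathrm{logit\,PPV}) = \frac{1-se}{se\,n_1} +
  \frac{sp}{(1-sp)\,n_0}$ and symmetrically for NPV. When the variance is
  undefined (e.g. NPV at $se = 1$) the point estimate is reported **without**
  bounds, with its method recorded as `none`; no bounds are fabricated, and
  zero-denominator metrics are returned as undefined rather than 0 or 1.
* With a single binary predictor, a bivariate logistic regression reduces
  exactly to the 2×2 odds ratio, so exposure associations are computed as
  $(ad)/(bc)$ with the Wald interval
  $\exp(\ln OR \pm z\sqrt{1/a + 1/b + 1/c + 1/d})$; any zero cell yields an
  explicit "undefined" rather than a continuity-corrected estimate.

Percentages print at one decimal with halves rounded up
(`round_half_up()`), the convention of clinical tables; R's default
round-half-even would print 14.85 as 14.8. Two table values sit on rounding
boundaries worth knowing about: the repeat-detection subgroup specificity is
$379/406 = 93.3497\ldots\%$, printing as 93.3 or 93.4 depending on
convention, and the exact upper accuracy bound for 368/414 is 91.7496%,
which a two-stage display (91.75 at two decimals, then one) presents as
91.8 while direct one-decimal rounding gives 91.7. Both full-precision
values are what the package reports.

Subgroup analysis supports two deliberately distinct semantics:
`cohort_filter` re-restricts the population (ventilated patients only, all
metrics recomputed within), while `positive_filter` keeps the full cohort
but narrows positivity (repeat-detected only, so single-notification
patients count as test-negative). Conflating the two changes denominators
and hence every estimate.

## The synthetic cohort generator

`simulation_config()` encodes the study conditions of a one-year
neurocritical-care cohort; `simulate_cohort()` draws patient records and a
*truth log* of each patient's designed class so engine output can be scored
against design (`calibration_check()`).

* **Classes.** Brain death with probability 0.019; otherwise a transient
  false-positive screening pattern with probability 46/406; otherwise a true
  negative. An optional stress mode (off by default) plants brain-death
  patients whose coma/pupil findings flicker only *between* ticks — designed
  false negatives, useful because a 12-hourly screen is structurally blind
  to sub-cycle episodes; the evaluated study observed none.
* **Demographics and stay.** Age truncated-normal 70.8 ± 14.8 (≥ 18) years,
  45.9% female, stay truncated-normal 9.1 ± 8.6 (≥ 1) days, admissions
  uniform over a year, and an admission-diagnosis mix dominated by ischemic
  stroke (70.1%), intracerebral hemorrhage (12.8%), seizure (8.2%) and
  meningoencephalitis (3.1%).
* **Charting.** All channels chart on a 4-hourly grid jittered ±1 h —
  comfortably inside the 12-h staleness windows, as ICU flowsheets are.
* **Brain-death course.** A random onset begins a persistent episode (RASS
  −5, GCS 3, both pupils absent, charted every 4 h) ending at the
  determination time, drawn onset + delay with delay truncated-normal
  3.6 ± 3.2 (≥ 0.5) days; the distribution family is a modelling choice —
  only mean, SD and a positive floor are constrained by the conditions being
  emulated. Because the episode spans at least one full cycle and charting
  outpaces staleness, every designed brain death is guaranteed at least one
  positive tick; stays are redrawn (boundedly) until they accommodate the
  course.
* **False-positive patterns.** A sedation-associated episode covering a run
  of $k$ consecutive ticks: $k = 1$ with probability $1 - 34/54$, else
  $k = 2 + \mathrm{NB}(\mathrm{size}=2, \mu=3.5)$ — a right-skewed count
  giving a median near the handful-of-notifications regime that repeat
  detection produces. Between episodes the baseline chart resumes (reactive
  pupils at worst 5 h apart), which guarantees the episode does not bleed
  into later ticks.
* **Baseline realism.** Sedated patients may chart coma-range scores (RASS
  −5…−2, GCS 3–8) with *reactive* pupils — this is exactly the
  sedation-mimics-coma structure that makes the rule's false positives
  plausible — while designed true negatives never chart an absent pupil, so
  they can never fire the combined rule (an invariant the tests scan for).
* **Covariates.** Analgosedation is a static per-patient covariate with
  rates 0.891 / 0.567 / 7⁄8 for false-positive / true-negative / brain-death
  patients — sufficient for the 2×2 odds-ratio analysis, which needs no
  medication time series. Ventilation (49/54 among designed positives,
  125/360 otherwise) and the ancillary-flag rates among positives (ICP 6/54,
  CPP 4/54, sodium absolute 7/54, sodium change 25/54, CPR 6/54) drive the
  corresponding event channels.

### What passing tests do and do not show

The generator reproduces the *screening-relevant statistical structure*:
prevalence, false-positive-pattern rate, repeat fraction, charting cadence,
covariate mix. It does **not** model physiological trajectories (pressures
and sodium are noise around plausible levels except where a flag is
designed), medication pharmacology, charting outages, inter-rater
disagreement in pupil assessment, or competing risks such as withdrawal of
life-sustaining therapy. Tests passing on synthetic cohorts therefore
demonstrate that the engine and statistics are *correct implementations of
the stated rule and estimators* under realistic data shapes — not that the
rule achieves any particular accuracy on real patients. Notably, real
repeat-notification gaps average above the cycle length because of charting
irregularities; on the simulator's dense charts, gaps are exact multiples of
12 h, which is the invariant the tests assert.

## Numerical and degenerate-input choices

* Timestamps are timezone-naive at minute resolution (internally pinned to
  UTC): flowsheet charting is minute-granular and the rule never needs finer.
* Ties in the event stream (same patient, time and kind) resolve to the last
  row in canonical sort order; the engine's vectorised lookup and the scalar
  `latest_value()` agree by construction and by an oracle test.
* The validator (`validate_record()`) reports *all* violations (field, event
  index, rule) and never throws; readers reject malformed lines with their
  line numbers.
* Interval functions validate $0 \le x \le n$, $n \ge 1$ and clamp nothing:
  degenerate requests error, degenerate *estimates* are reported as
  undefined.
* Problem sizes used by the checks: the end-to-end recovery run simulates
  2000 patients (≈ 1 M events) and finishes in well under a minute; coverage
  is assessed on a fixed $(n, p)$ grid — $n \in \{30, 50, 100\}$,
  $p \in \{0.1, 0.5, 0.9\}$ — against exact enumeration plus 2000 Monte-Carlo
  replicates per point; oracle equivalence of the full report is checked on
  100 random cohorts of up to 200 patients.

## Known limitations

* The engine evaluates one configuration per run; comparing staleness or
  anchor policies requires separate runs.
* The simulator's designed classes are mutually exclusive per admission; it
  does not generate patients who first show a transient pattern and later
  progress to brain death.
* Only the 2×2 odds ratio is provided for association analyses;
  multivariable adjustment is out of scope.
* The CLI reads whole files; streaming ingestion of live feeds is not
  attempted.
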