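---
title: "Quantifying relative hypotension: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying relative hypotension: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapdeficit)
```

## Overview

`mapdeficit` implements the computational pipeline of a pilot randomized
trial comparing individualized mean-arterial-pressure (MAP) targets — each
patient's own pre-illness MAP ± 2 mmHg — against standard care (default
65 mmHg) among vasopressor-treated ICU patients with shock. This vignette
explains the measurement model, every tunable that matters, the numerical
conventions the package commits to where the field leaves them open, and
what the synthetic-data validation does and does not establish.

## Pre-illness MAP and target assignment

A patient's usual blood pressure is reconstructed from 2–5 historical cuff
readings taken in usual health within 3 years of screening, each at least
12 h from every other selected reading. Each reading is converted with the
standard one-third pulse-pressure approximation
$\mathrm{MAP} = \mathrm{DBP} + (\mathrm{SBP}-\mathrm{DBP})/3$ and the
pre-illness MAP is their unweighted mean.

Two conventions needed fixing:

* **Spacing is enforced greedily from the most recent reading backwards** —
  a candidate is kept only if it is ≥ 12 h from every reading already kept.
  This matches a chart-tracing procedure that starts from the newest record
  and walks back.
* **Source preference**: clinic-type readings (ambulatory monitoring,
  outpatient or pre-admission clinics) are used alone whenever at least two
  of them qualify; observation-chart readings from the last 48 h of a prior
  hospitalization enter the pool only when they do not.

The individualized target band is the pre-illness MAP ± 2 mmHg, with the
centre limited to 55–95 mmHg. **The clamp is applied to the centre before
the band**, so an estimated pre-illness MAP of 100 mmHg yields a 93–97 band
rather than a one-sided 93–95 sliver: the quantity the protocol limits is
the *target*, and the ± 2 tolerance surrounds whatever target is set. The
alternative order (band, then clamp) is defensible; we chose the reading
that keeps every band 4 mmHg wide.

## Exposure metrics

All metrics are computed over the **active treatment window**: from T0 (the
start of continuous vasopressor/inotrope support) until the patient has been
weaned for at least 24 h or until 120 h, whichever is earlier. A
vasopressor-free gap shorter than 24 h followed by a restart keeps the
window open.

### Time-weighted average MAP-deficit

The percentage deficit at a MAP observation $m$ is
$d = 100\,(m_\mathrm{pre} - m)/m_\mathrm{pre}$; it is *signed*, negative
whenever the achieved pressure exceeds the pre-illness value. The summary
exposure is the time average of the **positive part** of the
piecewise-linear deficit signal (a positive incremental AUC):

$$\mathrm{TWA} = \frac{1}{t_n - t_1}\int_{t_1}^{t_n} \max\{0, d(t)\}\,dt.$$

Two implementations of "positive part" disagree on segments that cross
zero: clamping the sampled values before trapezoidal integration counts
half of each crossing segment's negative triangle as zero, while
integrating the exact positive part locates the zero crossing within the
segment. We integrate the exact positive part, with the crossing found
analytically in each segment. The package's test suite pins this choice
against an independent fine-grid Riemann oracle (step 0.01 h with generic
bisection refinement of crossings) to within $10^{-6}$ relative error over
1000 randomized series.

### Threshold-time fractions

"Percentage of time with > 20% deficit" and "percentage of time with
MAP < 65 mmHg" use a different convention, because they quantify *charted
state*, not integrated load: each inter-observation interval is classified
by its **left endpoint** (last observation carried forward), and

$$\%\,\mathrm{time} = 100 \cdot
\frac{\sum \text{classified interval durations}}
     {\sum \text{usable interval durations}}.$$

Intervals adjacent to a missing observation are excluded from numerator and
denominator alike — missingness is never interpolated for these metrics —
and leading/trailing gaps contribute nothing ("total time with available
MAP data" means intervals with both endpoints observed). With fewer than
two observations the fraction is undefined and returned as `NA`.

### Achieved MAP, daily summaries, deficit profiles

Achieved MAP is the trapezoidal time-weighted mean of the MAP signal over
the observed span — the natural continuous analogue of "time-weighted
average of 4-hourly values" that is exact for linear interpolation between
charted observations. Daily extremes use 24-h windows anchored at T0 (day 1
is hours 0–24), not calendar days, because T0 is the study clock's origin
throughout. The deficit-management profile crosses three deficit bins
(< 10%, 10–20%, > 20%, left-endpoint classified) with a vasopressor
*escalation* flag (norepinephrine-equivalent dose strictly greater at the
interval's right observation than at its left); occupancies are percentages
of classified time and sum to 100.

Where raw vasopressor agents are recorded, `ne_equivalent_dose()` converts
them to a norepinephrine-equivalent scale with an overridable table
(norepinephrine 1.0, epinephrine 1.0, phenylephrine 0.1 per µg/kg/min,
vasopressin 2.5 per U/min; dobutamine excluded as an inotrope) — a common
published equivalence, supplied as a configurable default because charted
doses usually arrive pre-converted.

## Renal outcomes

KDIGO staging is creatinine/RRT-based: stage 3 on RRT, creatinine ≥ 3×
baseline, or ≥ 353.6 µmol/l; stage 2 at ≥ 2× baseline; stage 1 at ≥ 1.5×
baseline or an absolute rise ≥ 26.5 µmol/l. Urine-output criteria are out
of scope — hourly urine volumes are not among the collected variables. With
only daily peak values, the 48-h qualifier of the absolute-rise criterion
is approximated by also counting a ≥ 26.5 µmol/l rise between adjacent
observed days; daily resolution is the finest available, so this is the
closest faithful reading.

When no measured pre-morbid creatinine exists (within 12 months before
admission, or from the current stay ≥ 7 days before ICU), the baseline is
back-estimated by solving the MDRD equation at an assumed eGFR of
75 ml/min/1.73 m² — coefficient 175, no race term, 0.742 for females —
the KDIGO appendix convention. Back-substitution reproduces eGFR 75 to
$10^{-6}$ relative error in the tests.

Endpoints:

* **New significant AKI**: peak stage over days 1–14 minus the entry stage
  ≥ 2, the entry stage being computed at the randomization creatinine —
  the window is anchored at T0 and the trial records creatinine at
  randomization, so that value defines "where the patient started".
* **MAKE-14**: death ≤ day 14, new RRT ≤ day 14, or creatinine ≥ 2× the
  *pre-morbid baseline* at the assessment day (day 14 or ICU discharge,
  whichever is earlier; the last daily peak at or before it). The
  randomization creatinine is deliberately *not* used here — it serves only
  as the denominator of the **peak percentage creatinine rise**, which is
  reported among RRT-free patients and left signed (a peak below the
  randomization value is a negative rise).

## Trial statistics

* **Fisher exact test** (binary outcomes): two-sided by the
  point-probability convention — the sum of hypergeometric probabilities of
  all tables, conditional on both margins, no more probable than the
  observed one, with $10^{-7}$ relative slack for floating ties. A
  degenerate margin admits one table; p = 1 by convention, logged.
* **Wilcoxon rank-sum** (continuous outcomes): exact enumeration when the
  combined sample is ≤ 20 and tie-free, otherwise the normal approximation
  with continuity and tie correction.
* **Mixed models**: for repeated daily measures (percentage deficit,
  achieved MAP, vasopressor dose, daily MAP extremes, daily peak
  creatinine), a REML random-intercept model with fixed effects for
  treatment, days from T0 to randomization, days since randomization, and
  treatment × time. CIs are Wald on the REML fit; Satterthwaite or
  Kenward–Roger degree-of-freedom corrections are out of scope, a known
  divergence risk from trial software at pilot sample sizes. Singular fits
  are flagged and refit by ML with a warning.
* **Group tables** report n (%) with Fisher p for binaries and median [IQR]
  with Wilcoxon p for continuous variables; IQRs are 25th/75th percentiles
  with linear interpolation (the default type-7 quantile; no quantile rule
  is mandated by the reporting conventions we follow).
* **Sample sizes**: the two-proportion calculator uses the classical
  pooled-null/unpooled-alternative normal formula, with rounding applied
  *once*, to the attrition-inflated total; z-quantiles at full double
  precision. With 20% vs 14%, α 0.05, power 0.80 and 2.5% attrition it
  returns 1260. The two-mean calculator,
  $n = 2(z_{1-\alpha/2}+z_{1-\beta})^2\sigma^2/\delta^2$ per group, returns
  40 in total for an 8-point difference at SD 9 — a published pilot figure
  of 50 for those inputs cannot be reproduced by this standard formula (the
  inflation rule, if any, is unstated); the calculator reports the formula
  value and we document rather than reconcile the discrepancy.

## The synthetic-cohort generator

The generator (`sim_config()` / `generate_trial()`) exists so that every
stage of the pipeline is exercised end to end without patient data. Its
defaults are the pilot-trial conditions: 37 patients across two sites with
22/15 enrolment weights, randomized within site by permuted blocks of
random sizes {2, 4}; pre-illness MAP ~ N(95, 8) mmHg; achieved MAP an AR(1)
process (lag-1 coefficient 0.6 at 4-h spacing, stationary SD 6 mmHg) around
77 mmHg in the standard arm — the documented real-world overshoot above the
65 mmHg default — and around the assigned target centre in the
individualized arm; log-normal support durations with median 90 h (between
the two arms' observed medians), truncated to 8–120 h; creatinine
trajectories whose daily upward-drift probability is logistic in the
patient's time-weighted deficit with an acute phase that resolves over the
first week; and an 11% 14-day mortality base rate. AR(1) around a policy
mean is deliberately the simplest process with realistic autocorrelation;
no physiological model is attempted or implied.

All randomness flows from one master seed through per-patient derived
substreams (and per-site substreams for randomization), so enlarging a
cohort never perturbs already-generated patients.

**Parameter recovery.** For a stationary normal MAP process the deficit is
$D \sim N(d, s)$ in percent, and the long-run time average of its positive
part has the closed form $E[\max(0, D)] = d\,\Phi(d/s) + s\,\phi(d/s)$
(`expected_twa_deficit()`). The validation study generates a 500-patient
cohort, computes each patient's generator-implied expected deficit from
that law, and requires the pipeline's measured between-arm median
separation to agree with the configured separation within a 2000-draw
bootstrap 95% CI of the median difference — plus strict ordering of the arm
medians in ≥ 95% of 100 seeded replicates. At these settings the configured
separation is ≈ 16 percentage points and the measured one ≈ 15.8.

**What passing does and does not show.** The generator emulates the data
*structure* (sampling grid, censoring, policy separation, exposure-linked
AKI risk, plausible marginal rates) — it does not emulate clinician target
overrides, informative missingness, within-day circadian structure,
non-stationary shock trajectories, or any fitted relationship to real
patient-level data (which are not public). Green tests certify that the
pipeline measures what the generator encodes; they say nothing about how
closely the generator matches any particular ICU.

Calibration-study sizes were chosen to keep the whole suite comfortably
interactive: 500 patients (and 100 replicates) for exposure recovery, 2000
null tables for the Fisher size check (the test is conservative; its
rejection rate sits near 0.03 against the nominal 0.05), and 200 null
replicates at 40 patients for mixed-model CI coverage, accepting Wald
intervals' slight anti-conservatism at that scale.

## Degenerate inputs and edge rules

* A single MAP observation: the time-weighted deficit degenerates to
  $\max(0, d)$ at that point and achieved MAP to the observed value;
  threshold-time fractions are `NA` (no interval exists).
* Empty series, empty vasopressor epochs, non-positive pre-illness MAP, and
  individualized assignment without a pre-illness MAP raise typed errors
  (`mapdeficit_empty_series`, `mapdeficit_empty_window`,
  `mapdeficit_contract_error`, …) rather than returning silent zeros.
* Eligibility screening treats missing optional criteria (no lactate drawn,
  unknown GCS) as *criterion not met*, never as an error: screening must
  proceed on partial data.
* A MAKE-14 assessment with no usable creatinine and no other positive
  component returns `FALSE` with a logged data-gap warning, keeping the
  composite monotone in its components.

## Known limitations

* Threshold-time conventions (left-endpoint attribution, both-endpoint
  denominators) and the exact positive-part integration are stated
  conventions validated against internal oracles and the constant-signal
  limit; charted trial computations could differ in either respect without
  that being knowable from published materials.
* KDIGO staging here ignores urine output, and the 48-h absolute-rise
  window is approximated at daily resolution.
* Mixed-model inference uses Wald CIs without small-sample df corrections.
* The generator's arm policy assumes the individualized arm *achieves* its
  target centre on average; real intervention arms undershoot when high
  targets are hard to reach, so real deficit medians in such an arm will
  exceed the generator's.
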