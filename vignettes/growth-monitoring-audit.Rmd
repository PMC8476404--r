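---
title: "Growth monitoring decision support and its audit: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth monitoring decision support and its audit: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdcgrowth)
```

## The problem

Paediatric development clinics (PDCs) follow high-risk infants — born
preterm, with low birthweight, or with other perinatal complications —
through a dense visit schedule in the first years of life. At every
visit a nurse weighs and measures the child and must translate the raw
numbers into a nutritional classification: length/height-for-age
(L/HFA), weight-for-length/height (WFL/H) and weight-for-age (WFA)
z-scores against a growth standard, plus the average daily weight gain
since the last visit. For preterm infants all of this must happen on
the *corrected* age scale. Each step is error-prone by hand, which
motivates tool support and, equally, a way to audit how completely and
accurately the assessment is being recorded in routine care.

`pdcgrowth` implements both halves:

* the **clinical algorithm** — corrected age, LMS z-scores with the
  restricted adjustment, interval growth, and the protocol's rule-based
  classification with traffic-light colours; and
* the **evaluation machinery** — visit-level completeness and
  concordance audits by exposure group (control/intervention x
  pre/post), child-level nutritional status at target corrected ages,
  and difference-in-difference (DiD) estimation with facility-clustered
  standard errors,

together with a seeded synthetic EMR generator so the full pipeline is
exercisable without any external data.

## The clinical algorithm

### LMS z-scores

A growth reference in the LMS parameterisation stores, per value of an
index (age in days, or length in cm for WFL/H), a Box-Cox power $L$,
median $M$ and coefficient of variation $S$. A measurement $y$ maps to

$$ z = \frac{(y/M)^L - 1}{L\,S} \quad (L \neq 0), \qquad
   z = \frac{\log(y/M)}{S} \quad (L = 0). $$

Parameters are interpolated linearly between adjacent reference rows
(the behaviour of the standard WHO macros), with no extrapolation
beyond the table's span. For the weight-based indicators (WFA, WFL/H)
the package applies the WHO *restricted* adjustment beyond $|z| = 3$:
above 3,

$$ z^* = 3 + \frac{y - \mathrm{SD3}}{\mathrm{SD3} - \mathrm{SD2}}, $$

with the mirrored form below $-3$, where $\mathrm{SD}k$ is the
measurement at $z = k$ from the inverse transform
$y = M (1 + L S z)^{1/L}$. This treats the tail linearly in
measurement units and avoids the Box-Cox tails' sensitivity to extreme
entries. L/HFA is never adjusted, matching the convention of the WHO
igrowup macros. Inside $[-3, 3]$ the restricted and raw values agree
exactly, and the raw (unrestricted) value is retained alongside for
plausibility screening.

### Corrected age

For an infant born before 37 completed weeks with documented
gestational age $g$ (weeks), corrected age is chronological age minus
$\mathrm{round}(7\,(40 - g))$ days; it can be negative before the due
date. Term children use chronological age unchanged. A preterm child
whose gestational age is undocumented falls back to chronological age
with a `correction_unavailable` flag: such children still count as
preterm (for instance in the corrected-age completeness denominator)
but their gold-standard assessment runs on the fallback age, since no
correction can be computed. Ages are kept in days throughout; where a
threshold or target is stated in months, one month is 30.4375 days
(365.25 / 12).

### Classification rules

The protocol's standardized definitions drive `classify_zscore()` and
`classify_interval_growth()`:

* z-score indicators: `normal` at $z \ge -2$, `moderate` at
  $-3 \le z < -2$, `severe` at $z < -3$ — both lower bounds closed, so
  $z = -2$ is normal and $z = -3$ moderate;
* not-applicable conditions, checked *before* any z threshold, reflect
  the physical limits of the growth-chart axes: negative corrected age
  (any indicator), length below 42 cm (L/HFA), length below 45 cm or
  weight below 1.6 kg (WFL/H), weight below 1.4 kg (WFA);
* interval growth (g/day, signed) is adequate when it meets the
  corrected-age band's threshold: 20 in $[0,3)$ months, 15 in $[3,6)$,
  10 in $[6,8)$, 6 in $[8,12)$, 5 in $[12,16)$, 4 in $[16,24)$; not
  applicable at negative corrected age, at or beyond 24 months, or
  when no previous weight exists. The comparison is `>=`, so a rate
  exactly at the threshold is adequate. The source protocol prints the
  WFA weight limit as "1.4 g" and the middle bands with an inverted
  relational sign; the package reads these as 1.4 kg and as
  left-closed, right-open bands partitioning $[0, 24)$ months, the
  only readings consistent with a live infant and a partition.

Colours mirror the tool's display: green for normal/adequate, yellow
for moderate, red for severe or inadequate growth.

`assess_visit()` composes the above for one visit; `assess_cohort()`
runs a whole visit table, linking each visit to the child's most
recent earlier visit *with a recorded weight* (the "weight at last
visit") and flagging first visits. A visit is marked implausible when
any raw z-score lies beyond $\pm 5$; the raw scale is used because the
restricted adjustment deliberately compresses exactly the tails the
screen is looking for.

## The audit layer

Visits are cross-classified into four exposure groups (arm x period).
Before any audit, `apply_cohort_filters()` drops visits outside both
study windows and post-period visits of children who enrolled in the
pre period, which would otherwise contaminate the design.

**Completeness** is the share of visits where the nurse recorded a
response, per group and metric. A recorded "not applicable" is
complete (it is a clinical judgement, not an omission), and interval
growth counts whether recorded as a category or as a continuous g/day
value. The corrected-age metric is tallied among preterm children's
visits only. An optional cutover date restricts the L/HFA metric to
standard growth-assessment visits from that date on, mirroring a
recording-practice change in which L/HFA stopped being charted at
urgent-care visits; the restriction is off by default.

**Concordance** compares each nurse-recorded category with the class
recomputed from the raw measurements. The denominator per metric is
the set of nurse-assessed visits. A response is discordant when (1)
the categories differ, (2) the raw data are insufficient to validate
it — some input needed for the gold class is missing or outside the
reference span — or (3) the visit's measurements are implausible (raw
$|z| > 5$). For interval growth, each child's first visit is excluded
(record systems typically lack the pre-enrollment weight), and a
continuous-only entry is concordant iff classifying the recorded
g/day value against the child's band reproduces the gold
adequate/inadequate call; no numeric tolerance is applied, since any
value on the correct side of the threshold classifies correctly. A
nurse "not applicable" is concordant exactly when a gold
not-applicable condition holds. Percentages are rounded half-up to
integers, matching the audit-table presentation (`round_half_up()`).

## Nutritional status at target ages

`cohort_outcomes()` evaluates stunting (L/HFA $z < -2$), wasting
(WFL/H $z < -2$), underweight (WFA $z < -2$) and inadequate interval
growth at target corrected ages (defaults 2 and 6 months), among
children enrolled before 2 months corrected age. For each child and
target the visit minimising the distance between corrected age and
target is selected, provided it lies within one month (30.4375 days);
ties between equidistant visits go to the earlier visit, making
selection deterministic and independent of file order. Flags are
missing — and the child leaves that outcome's denominator — when the
indicator's inputs are incomplete, the visit is implausible, or (for
interval growth) no previous weight exists. Corrected age drives the
target for all children; for term children it coincides with
chronological age.

## Difference-in-difference

`did_fit()` estimates, per binary outcome,

$$ y_i = \beta_0 + \beta_1\,\mathrm{arm}_i + \beta_2\,\mathrm{post}_i
       + \beta_3\,(\mathrm{arm} \times \mathrm{post})_i + \varepsilon_i $$

by OLS — a linear probability model, so $\beta_3$ is directly the
difference-in-difference in percentage points/100. In this saturated
form $\beta_3$ equals the four-cell closed form
$(p_{I,\mathrm{post}} - p_{I,\mathrm{pre}}) -
 (p_{C,\mathrm{post}} - p_{C,\mathrm{pre}})$ exactly, which the tests
assert to $10^{-10}$. Inference uses a cluster-robust sandwich
variance over facilities. The small-sample correction is `CR1`,
scaling the meat by $\tfrac{G}{G-1}\,\tfrac{n-1}{n-k}$ with a
$t_{G-1}$ reference distribution — the convention of Stata's
`vce(cluster)`, the de facto standard in applied DiD work of this
kind; `CR0` (no correction) is available as configuration. The
facility-mix sensitivity analysis adds facility type (hospital vs
health centre) as a covariate. A simulation test documents — without
fixing — the known small-sample behaviour of this estimator: under a
null interaction with facility random effects and 20 clusters, the
rejection rate at $\alpha = 0.05$ stays within $[0.03, 0.09]$ over
1,000 replicates.

## The synthetic EMR generator

`simulate_cohort()` produces children, visits and a truth table with
the statistical structure the audit and DiD stages assume. Its
defaults are chosen once to describe a realistic two-district
programme of this kind and are not fitted quantities:

* cohort sizes 214 / 151 / 288 / 227 children across the four
  exposure groups, enrolled in two six-month windows separated by a
  six-month gap;
* nine facilities (one hospital plus three or four health centres per
  arm), with a per-group probability of hospital enrolment that shifts
  strongly toward health centres in the intervention post period,
  emulating concurrent decentralisation;
* a preterm-heavy case mix (57% below 37 weeks; gestational age
  truncated-normal within strata; 15% of preterm children lack a
  documented gestational age and arrive as referrals), birthweight
  declining about 210 g per week below 40;
* the standard follow-up schedule (1, 2, 3 weeks; 1, 2, 4, 6, 9, 12
  months of chronological age) with 85% attendance per scheduled
  visit;
* latent growth: per-child length-for-age and weight-for-age z
  intercepts drawn from normals (means near $-1.9$, reflecting a
  high-risk population in which roughly half the infants sit below
  $-2$), with AR(1) visit-to-visit noise (correlation 0.7) capturing
  growth tracking; true lengths and weights come from inverting the
  reference at the visit's corrected age (clamped at zero before the
  due date), plus measurement noise (30 g, 0.3 cm) and rounding to
  the precision of routine charting;
* nurse behaviour: per-metric, per-group completion probabilities
  (defaults shaped like the audit's observed recording patterns, with
  a large intervention-post gain), a per-group misclassification
  probability (a recorded category is replaced by a uniformly chosen
  different one), occasional continuous-only interval entries, and a
  small probability (0.5%) of a slipped-decimal weight producing an
  implausible record.

The generator runs every recorded visit through the same
`assess_visit()` gold standard the audit uses, so recovery tests have
exact targets: with completion probability $p$ and misclassification
probability $q$ in an otherwise clean scenario, completeness estimates
recover $p$ and concordance recovers $1 - q$ to binomial accuracy.
One interaction deserves note: because the latent length and weight
trajectories are drawn independently, extreme combinations (a heavy
z for one, a light z for the other) occasionally produce
weight-for-length values beyond raw $|z| = 5$, which the concordance
audit then correctly counts as discordant under rule (3). The
recovery scenario therefore uses a moderate latent spread
($\mu = -1$, $\sigma = 0.8$) so that recorded rates remain the only
source of incompleteness and discordance; with the defaults the small
residual gap is real audit behaviour, not estimator bias.

What the generator does *not* emulate: demographic covariates
(education, socioeconomic category), seasonality, facility-level
differences in measurement quality, informative missingness (a
nurse's decision to record is independent of the child's status given
the group), and real WHO reference curves. Passing tests therefore
show the algorithmic layer is correct under the declared statistical
structure, not that any particular field deployment behaved this way.

## References: bundled versus real

The bundled reference set (`synthetic_reference()`) is built from
smooth parametric curves — exponential-saturation medians for
length-for-age and weight-for-age, and a weight-for-length median
constructed by composition so the three indicators are mutually
consistent. It is deliberately synthetic and clearly labelled as such:
close enough in location and spread for simulation and testing, but
not the WHO 2006 Child Growth Standards. Real WHO LMS text files load
through `read_lms_table()`, which accepts tab- or comma-delimited
columns `sex | index | L | M | S` with `1/2` or `m/f` sex coding, at
any grid granularity (the interpolation is agnostic to daily versus
monthly tables). The same applies to the small-for-gestational-age
percentile interface: `is_sga()` takes any table of 10th-percentile
birthweights by sex and gestational age, and the bundled
`synthetic_birthweight_p10.csv` fixture is a synthetic stand-in, not
the INTERGROWTH-21st standard.

## Numerical choices and edge cases

* One month = 30.4375 days everywhere a month-valued quantity is
  converted (bands, target ages, selection windows).
* Report percentages round half *up* to integers; `round_half_up()`
  is used rather than R's banker's rounding so that 62.5 prints as 63.
* The weeks-early correction rounds $7(40 - g)$ to the nearest whole
  day, accepting gestational ages in whole weeks or weeks + days.
* Boundary behaviour is pinned by tests at $\pm 10^{-12}$ of every
  cut: $z = -2$ and $z = -3$ belong to the milder class; exactly 24
  months corrected age is already not-applicable for interval growth;
  a rate exactly at a band threshold is adequate.
* Tie between two visits equidistant from a target age: the earlier
  visit wins.
* `interpolate_lms()` refuses to extrapolate; out-of-span indices
  yield missing z-scores (never clamped values), which downstream
  layers treat as "insufficient data".
* The inverse LMS transform rejects the argument region
  $1 + LSz \le 0$ as a domain error rather than returning complex or
  negative measurements.
* Degenerate DiD designs (a single cluster, an empty cell) raise
  typed errors instead of returning fragile estimates.

## Problem sizes in the test suite

The packaged tests run the worked examples at their natural sizes
(hundreds of visits), the rule-engine grids exhaustively (thousands of
boundary combinations), rate recovery on a cohort of about 5,000
retained visits, DiD recovery at 20 facilities x 4,000 children, and
the null-rejection study at 1,000 replicates of 400 children — sizes
chosen so each check has the statistical resolution it claims (3
Monte-Carlo standard errors, or exactness) while the whole suite runs
in a few minutes on one core.

## Known limitations

* The restricted adjustment and the $\pm 5$ plausibility screen are
  conventions; other deployments use different extreme-value rules.
* The linear probability model can fit probabilities outside
  $[0, 1]$; it is used deliberately for its percentage-point
  interpretation, with clustered errors carrying the inference.
* With few clusters (here 9 facilities in the emulated design) even
  CR1 + $t_{G-1}$ is only approximately sized; the null-simulation
  test documents the achieved size rather than guaranteeing 5%.
* The synthetic references must not be used for clinical work.
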