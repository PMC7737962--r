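---
title: "Deriving a birth cohort from hospital episodes and quantifying linkage error"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving a birth cohort from hospital episodes and quantifying linkage error}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hesbirths)
```

## The problem

Administrative hospital data can stand in for a national birth register:
every NHS-funded birth in England leaves a birth episode in the admitted
patient care extract, and a pseudonymised person identifier (generated
from NHS number, local patient identifier, date of birth, postcode and
sex) lets records be chained into longitudinal histories and joined to
civil death registrations. The catch is that the identifier machinery
itself changed over time. Three changes matter for babies:

* **Q4 2002** — NHS numbers issued at birth notification (the NN4B
  service), instead of weeks later at civil registration. Before this,
  a birth episode often lacked an NHS number, so the baby's *next*
  admission could generate a fresh person ID and the follow-up record
  silently detached from the birth.
* **Q3 2009** — the online registration system (RON) added validation
  checks at birth and death registration.
* **Q2 2013** — the data provider corrected an extraction error that
  had blanked postcode (and postcode-derived deprivation scores) on all
  birth episodes.

Linkage failure is invisible in the data itself: a detached follow-up
record just looks like a different child. It becomes visible in
*outcome trends*: the proportion of babies with any readmission in
infancy, and infant mortality, both jump when linkage improves. This
package builds the cohort, computes those outcomes, fits the segmented
regression that quantifies the jumps, and — because the real extracts
are access-restricted — ships a synthetic generator that reproduces the
failure mechanisms with known ground truth, so the whole pipeline is
testable and parameter recovery is measurable.

## Pipeline anatomy

```{r, eval = FALSE}
cfg <- scenario_config()           # the default simulated study
res <- run_pipeline(cfg)           # simulate -> cohort -> outcomes -> fit
res$fit
```

### Cohort construction

`identify_birth_episodes()` uses deliberately broad union criteria — an
episode qualifies as a birth if *any* of episode type, admission method
or a live-born-infant diagnosis (ICD-10 Z38 family, matched on dot-free
prefixes) fires — because any single field is incompletely recorded.
Children with several qualifying episodes keep the earliest.
`apply_exclusions()` then drops multiple births (same-sex siblings
sharing identifiers are a known false-match risk), stillbirths, and
unfinished episodes, in a fixed order with each child counted once, so
the exclusion ledger reconciles exactly: input rows = retained + sum of
reasons. The exact national selection and cleaning lists live in
restricted supplementary material, so every code list and range in
`birth_ruleset()` is a configurable stand-in default.

Cleaning is value-level: birth weight outside 200–7000 g, gestational
age outside 22–44 completed weeks and maternal age outside 10–60 years
are set missing rather than dropping the child, plus a joint
weight-for-gestation envelope (per gestation band) that blanks both
members of an individually-plausible but mutually-implausible pair.
A `drop_implausible` switch excludes such children instead, feeding the
`implausible_values` ledger row. England residency is judged on the
region code, *not* postcode — postcode is exactly the field blanked by
the 2013 extraction error. Ethnicity is completed as the most frequent
value across the child's linked first-year records (ties to the
earliest), and the deprivation quintile as the earliest non-missing
first-year recording.

### Admissions and the readmission outcome

A hospital admission is a continuous period under hospital care;
transfers and admissions within 1 day of each other count as one
admission. `build_admissions()` implements this as an interval union
with 1-day tolerance (a single sorted pass with a running maximum
end-date; tested against a brute-force transitive-closure oracle). The
gap is measured in whole calendar days, so a next-day admission merges
and a day-after-next one does not; an overlap on the same day always
merges. Episodes missing an end date take end = start for merging;
episodes with end before start are rejected and logged.

The birth admission is the admission containing the birth episode — by
construction it absorbs transfers to neonatal intensive care within a
day of birth. A child is *readmitted* if any other admission starts
after birth-admission discharge and within days 0–364 of life (a
365-day window regardless of leap years; the admission may end later).
Cohorts are stratified at a 7-day birth admission, the hypothesis being
that identifiers can be corrected during a long stay.

### Mortality linkage

An infant death is recorded from a register row linking by person ID,
or from a discharge method of "died", at age 0–364 days (day of birth
is day 0, so the neonatal band 0–27 covers the first 28 days). A death
seen both ways within ±1 day (registration jitter) is one death, with
date and causes taken from the register; discharge-only deaths have no
cause codes — which is precisely the information lost when the register
link fails. Neonatal and post-neonatal rates share the cohort
denominator, so they sum to the infant rate exactly. Deaths after day
364 fall outside follow-up and are ignored; register rows dated before
birth are rejected and logged.

`linkage_diagnostics()` reports the two complementary failure rates per
year — cohort deaths with no register link, and register deaths
matching no hospital episode — and `weighted_linkage_summary()` pools
them over periods, weighting years by deaths so the summary equals the
pooled-count percentage. One asymmetry is unavoidable: an *unlinked*
register row carries no person link and the mortality schema carries no
date of birth, so the register side is grouped by year of death (for
infant deaths, almost always the birth year or the year after).

### The segmented regression

The quarterly proportion series (in percentage points) is modelled as

$$y_t = \alpha + \beta T_t + \theta_2 Q_{2t} + \theta_3 Q_{3t} + \theta_4 Q_{4t}
  + \sum_{k=1}^{3} \delta_k S_{kt}
  + \sum_{k=1}^{3} \gamma_k S_{kt}\,(T_t - T_k) + \varepsilon_t$$

with $T_t$ the quarter index, $Q_q$ quarter-of-year indicators, $S_k$ a
step that is 0 before and 1 from change point $k$, and slope-change
interactions centred at their change point. Centring makes $\delta_k$
the pure level shift at $T_k$ — observed minus the value expected by
extrapolating the pre-change trend — and `itsa_counterfactual()`
returns exactly that decomposition (observed = expected + shift, an
identity of the fit). Segment slopes reconstruct as
$\beta, \beta+\gamma_1, \beta+\gamma_1+\gamma_2, \ldots$

Choices made where the design was open:

* **Time unit.** Effects are reported per annual quarter, so the
  continuous time variable defaults to the quarter index; a yearly unit
  (`time_unit = "year"`) is a linear reparameterisation giving
  identical shifts.
* **Estimation.** Plain OLS on the aggregate percentage scale (a linear
  probability model for a proportion of tens of thousands of births per
  quarter, whose binomial noise is tiny and near-Gaussian).
  Autocorrelation-robust (Newey–West) standard errors are available
  behind `robust = TRUE` but are not the default.
* **Identifiability.** The design requires at least two quarters per
  era; otherwise a step and its interaction are collinear and the fit
  refuses rather than silently dropping terms.

## What the generator emulates

`scenario_config()` fixes the simulated study conditions. Defaults:
births 1998Q1–2015Q4, 1000 per quarter; a flat true readmission
probability of 0.20 (piecewise-linear knots are available); infant
death probability 0.0042 with 70% of deaths neonatal, 90% in hospital —
values in the range national statistics report for this period; birth
admissions are 0–6 days long with 10% lasting 7–30 days. Calendar
dates are quarter midpoints plus ±40 days of uniform jitter, which
keeps every date inside its quarter.

The two linkage mechanisms are:

* **Person-ID continuity**, per era: with probability
  `p_person_id_continuity[era]` a child's post-birth records carry the
  birth person ID; on failure *all* of them share one fresh ID (the
  identifier is generated once per identifier set, so failure is a
  child-level, not record-level, event). Defaults are 0.70 before NN4B
  and 1 after — the pre-NN4B deficit is not directly measurable from
  published sources, so it is a free parameter; 0.70 against a true
  readmission probability of 0.20 implies a 6.0-pp level shift at the
  first change point, the magnitude the readmission trend displays.
  The generator records the implied shifts in `implied_shifts_pp`.
* **Register linkage**, per era: with probability `p_ons_link[era]` a
  death registration carries the birth person ID; otherwise its person
  field is null, while an in-hospital death still sets discharge method
  "died". Defaults 0.67/0.90/0.95/0.95 mirror the observed era pattern
  of discharge-only death percentages.

In-hospital deaths at ages within the birth stay are recorded on the
birth episode; later ones get a terminal admission (start two days
before death), whose person ID obeys the continuity mechanism. A
realised readmission is placed at least two days after birth
discharge — a next-day admission is, by the pipeline's own merge rule,
a transfer absorbed into the birth admission, so a "true readmission"
there would be unobservable by construction. At most one readmission is
generated per child: the outcome is binary, so one is the minimal
sufficient structure. Baby-tail missingness is per-field and per-era;
the postcode error window blanks postcode and deprivation quintile on
birth episodes only; cause codes are dropped from register rows at ages
28–30 days with probability 0.75, emulating the extraction defect
concentrated just past the neonatal boundary.

A single integer seed drives one PRNG stream consumed in a fixed
per-child order *regardless of outcomes*, so paired runs sharing a seed
are coupled draw-for-draw: lowering one probability flips only the
children whose draw falls between the old and new values. This makes
monotonicity checks sharp (era-0 continuity down ⇒ era-0 observed
readmission down, later eras byte-identical) and output files
byte-identical across reruns.

What the generator does **not** emulate — and therefore what passing
tests cannot show about real extracts: maternal delivery episodes and
mother–baby linkage, multiple births, false-positive matches (IDs are
never wrongly shared), seasonality in birth volumes or outcomes,
secular trends in mortality, migration in and out of England during
infancy, and any correlation between risk factors and outcomes.
Readmission and death processes are independent Bernoulli draws given
the quarter, which is the minimal structure the trend analysis needs.

## Numerical and bookkeeping conventions

* Quarters are integers ($4\,\mathrm{year} + \mathrm{quarter} - 1$), so
  trend arithmetic is exact; labels look like `"2002Q4"`. Era $k$ runs
  from change point $k$ (inclusive) to the next.
* The exclusion ledger's `not_birth` row counts episode *rows* not
  selected as a candidate birth (including surplus qualifying episodes
  of a child); other reasons count children. That is the only
  convention under which the ledger reconciles exactly against an
  episode table, and it is asserted on every `build_cohort()` run.
* Percentages are displayed at 1 decimal place and rates at 2, with
  full precision retained in the returned tables; every displayed ratio
  is recomputable from its displayed numerator and denominator.
* The reference tables shipped under `inst/extdata/` are published
  national comparison figures (per-year cohort and singleton birth
  counts, per-year infant-death linkage percentages, and headline
  totals), so coverage and linkage arithmetic run without any download.
  The packaged coverage reference supplies singleton counts directly;
  a `total_births` column with a 0.97 singleton ratio is supported for
  user-supplied tables.

## Problem sizes used in the test-suite

Unit fixtures are a handful of hand-written episodes. Property checks
run the admission merge against a brute-force transitive-closure oracle
on 1000 random episode sets (up to 12 episodes each) and the
segmented fit against noise-free series generated from random
coefficient vectors, where recovery is exact. Parameter-recovery runs
use the default study conditions — 72 quarters of 1000 births — with
200 Monte-Carlo replicates for the NN4B level shift (mean recovered
shift within Monte-Carlo error of the implied 6.0 pp, and nominal 95%
interval coverage) and single runs for the per-era discharge-only death
percentages (binomial tolerance around $1 - $ `p_ons_link`). The same
quantities, at 20 replicates, are what `scripts/acceptance.R`
recomputes and writes as JSON.

## Limitations

The package analyses one outcome series at a time with a fixed
three-change-point design; it offers no ARIMA or state-space
alternatives and no inference beyond the single linear model. The
synthetic person IDs are never *wrongly merged*, so false-match error —
the reason multiple births are excluded in the first place — is
represented only by its exclusion rule, not simulated. Register rows
carry no date of birth, so register-side diagnostics group by death
year. Real-extract idiosyncrasies (provider-level coding drift,
mid-year identifier corrections, partial-year extracts) are out of
scope; the generator's era boundaries are sharp where reality was
gradual.
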