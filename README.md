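# hesbirths

Tools for deriving a national cohort of singleton live births from
Hospital Episode Statistics (HES)-style admitted-patient-care extracts,
and for quantifying how changes to patient-identifier collection
affected linkage of births to follow-up hospital and mortality records.

## The problem

In England, every NHS-funded birth leaves a birth episode in the
hospital admissions database, and a pseudonymised person identifier
(derived from NHS number, local identifier, date of birth, postcode and
sex) chains records into longitudinal histories and joins them to ONS
death registrations. That makes a whole-country birth cohort possible —
but the identifier machinery changed three times (NHS Numbers for
Babies at birth notification from Q4 2002; the online registration
system RON from Q3 2009; correction of a postcode extraction error from
Q2 2013), and linkage failure is invisible in the data itself. It
surfaces only as artefacts in outcome trends: infant readmission
proportions and mortality rates jump when linkage improves.

`hesbirths` is for epidemiologists and data scientists working with
episode-level administrative extracts. It implements:

* **cohort construction** — broad union criteria for identifying birth
  episodes, ordered exclusions (multiples, stillbirths, unfinished
  episodes) with an exactly reconciling ledger, value-level risk-factor
  cleaning, and longitudinal completion of ethnicity and deprivation;
* **episode→admission merging** — interval union with 1-day transfer
  tolerance, and the infant readmission outcome (any admission after
  birth-admission discharge within days 0–364);
* **mortality linkage** — infant deaths from register links and/or a
  discharge method of "died", neonatal (0–27 d) / post-neonatal
  (28–364 d) rates per 1000 live births, and two-sided
  linkage-failure diagnostics;
* **interrupted time-series analysis** — segmented OLS regression of
  the quarterly readmission series around the three change points:

  $$y_t = \alpha + \beta T_t + \textstyle\sum_q \theta_q Q_{qt}
    + \sum_{k=1}^3 \delta_k S_{kt}
    + \sum_{k=1}^3 \gamma_k S_{kt}(T_t - T_k) + \varepsilon_t$$

  with interactions centred at their change point, so each
  $\delta_k$ is the pure level shift (observed minus the value expected
  from the pre-change trend) and each $\gamma_k$ a slope change in
  percentage points per quarter;
* **a synthetic-data generator** — HES-like episode tables and ONS-like
  mortality tables with known ground truth, reproducing era-dependent
  person-ID discontinuity, register-link failure, baby-tail
  missingness and the postcode error window, so the full pipeline runs
  and is testable with no access to restricted data.

## Worked example

The default scenario simulates 1000 births per quarter over 1998Q1 to
2015Q4 with a flat true readmission probability of 0.20 and pre-NN4B
person-ID continuity of 0.70 — so the generator-implied level shift at
the first change point is 0.20 × (1 − 0.70) = 6.0 percentage points.

```r
library(hesbirths)
res <- run_pipeline(scenario_config(), quiet = TRUE)
res$fit
#> Interrupted time-series fit (OLS SEs), time unit: quarter
#> Change points: 2002Q4, 2009Q3, 2013Q2
#> Baseline slope: -0.038 pp per quarter
#>   2002Q4: level shift +6.28 pp, slope change +0.052 -> segment slope 0.014
#>   2009Q3: level shift -0.58 pp, slope change +0.158 -> segment slope 0.172
#>   2013Q2: level shift -0.94 pp, slope change -0.259 -> segment slope -0.087
```

The fitted level shift at 2002Q4 (+6.28 pp here; estimates at other
seeds scatter around 6.0 with a standard error near 0.8) recovers the
simulated linkage deficit; the shifts at the later change points, where
the generator changes nothing, are statistically indistinguishable from
zero. The summary report makes the mechanism visible end to end:

```r
res$report
#> Births: 71,652
#> Readmitted in infancy: 13,200 (18.4%)
#> Infant deaths: 254 (3.54 per 1000 live births; 168 neonatal, 86 post-neonatal)
#>   2002Q4: observed 19.9%, expected 13.6%, shift +6.3 pp
#>   2009Q3: observed 18.9%, expected 19.4%, shift -0.6 pp
#>   2013Q2: observed 21.2%, expected 22.1%, shift -0.9 pp
#>   deaths 1998-2002: 14% identified from discharge method only
#>   deaths 2003-2009: 9% identified from discharge method only
#>   deaths 2010-2015: 5% identified from discharge method only
#>   deaths overall: 9% identified from discharge method only
```

Before NN4B the observed readmission proportion sits near
0.20 × 0.70 = 14% although the true proportion is 20% — a fifth of
follow-up records have detached from their births — and a larger share
of deaths is visible only through the hospital discharge method. The
infant mortality rate is correspondingly under-ascertained relative to
the generating 4.2 per 1000.

Real extracts enter the same way: read episode and mortality tables
with `read_hes_table()`, then `build_cohort()`,
`build_admissions()`, `readmitted_in_infancy()`,
`detect_infant_deaths()`, `quarterly_readmission_series()` and
`fit_itsa()` compose exactly as `run_pipeline()` does. Coverage against
national birth statistics comes from `coverage_table()`; packaged
per-year reference figures for England 1998–2015 are available via
`hes_reference_births()` and `hes_reference_death_linkage()`.

See the vignette (`vignettes/linkage-error-pipeline.Rmd`) for the model
details, the generator's mechanisms and defaults, and known
limitations.

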