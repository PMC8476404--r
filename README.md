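# pdcgrowth

Growth-monitoring decision support and audit machinery for paediatric
development clinics (PDCs) — follow-up programmes for high-risk
infants born preterm, with low birthweight, or with other perinatal
complications.

The package implements two things that belong together:

1. **The clinical algorithm** a growth-monitoring tool automates at
   each clinic visit: corrected gestational age, anthropometric
   z-scores (length/height-for-age, weight-for-length/height,
   weight-for-age) computed by the LMS method
   `z = ((y/M)^L − 1)/(L·S)` with the WHO restricted adjustment
   beyond ±3 for weight-based indicators, interval weight gain in
   g/day, and the protocol's rule-based classification
   (normal / moderate / severe, adequate / inadequate, with
   not-applicable guards and traffic-light colours).
2. **The evaluation framework** for auditing such a tool against EMR
   extracts in a pre/post × control/intervention design: visit-level
   completeness and nurse-vs-gold-standard concordance tallies per
   exposure group, child-level prevalence of stunting / wasting /
   underweight / inadequate growth at 2 and 6 months corrected age,
   and difference-in-difference estimation via linear probability
   models with facility-clustered (CR1) robust standard errors.

A seeded synthetic EMR generator (`simulate_cohort()`) reproduces the
cohort structure — visit schedules, preterm case mix, nurse recording
behaviour with missingness, misclassification and implausible
entries — so the entire pipeline runs with no external data. Bundled
growth references are smooth synthetic curves (clearly labelled as
such); real WHO 2006 LMS text files are drop-in via
`read_lms_table()`.

See `vignettes/growth-monitoring-audit.Rmd` for the full methods
account.

## A worked example

Assess one visit of a preterm girl (born 2018-08-10 at 32 weeks,
seen 2018-12-10 weighing 4190 g, 55.2 cm, previous weight 3640 g a
month earlier):

```r
library(pdcgrowth)
refs <- synthetic_reference()

child <- list(child_id = "C042", birth_date = as.Date("2018-08-10"),
              gestational_age_weeks = 32, referred_as_preterm = TRUE,
              sex = "female")
prev  <- list(visit_date = as.Date("2018-11-10"), weight_g = 3640)
visit <- list(visit_date = as.Date("2018-12-10"), weight_g = 4190,
              length_cm = 55.2)
assess_visit(child, visit, prev, refs)
```

```
chronological_age_days    122
corrected_age_days        66          # 122 − round(7·(40 − 32))
z_lhfa                    -0.243
z_wflh                    -1.771
z_wfa                     -1.541
interval_growth_g_per_day 18.33       # (4190 − 3640) / 30 days
class_lhfa                normal
class_wflh                normal
class_wfa                 normal
class_interval            inadequate  # 18.3 < 20 g/day for < 3 months
colour_wfa                green
implausible               FALSE
```

All three z-scores are above −2 (normal, green), but the child gained
only 18.3 g/day when the protocol expects ≥ 20 g/day below 3 months
corrected age — the interval-growth flag is the one that fires, which
is exactly the kind of signal interval monitoring adds over static
z-scores.

Audit a simulated two-district cohort and recover a known
intervention effect:

```r
cfg <- sim_config(seed = 42)
sim <- simulate_cohort(cfg, refs)
fv  <- apply_cohort_filters(sim$visits, sim$children)
assessed <- assess_cohort(sim$children, fv, refs)
report_wide(audit_completeness(assessed, sim$children))
#>            metric ... control_post_pct ... intervention_post_pct
#> 3   corrected_age                   52                        63
#> 4            lhfa                   58                        84
#> 6             wfa                   69                        93
#> 7 interval_growth                   80                        91

rows <- simulate_did_scenario(seed = 43, n_facilities = 20,
                              children_per_cell = 100,
                              base_prob = 0.4, interaction_effect = 0.15)
did_fit(rows, "recovery")
#> Difference-in-difference: recovery
#>   interaction = +0.1640 (16.4 pp), clustered SE = 0.0296, p = 2.365e-05
#>   n = 4000 observations, 20 facility clusters (CR1)
#>   cell means: C-pre 0.419, C-post 0.408, I-pre 0.392, I-post 0.545
```

The completeness audit shows the simulated intervention-post group
recording far more assessments (the generator's defaults encode that
design), and the DiD fit recovers the generating 15-pp interaction
within sampling error.

A thin command-line driver covering the same pipeline
(`simulate | assess | audit | outcomes | did | report`) ships in
`inst/cli/pdc.R`:

```sh
Rscript inst/cli/pdc.R simulate --out-dir sim --seed 3
Rscript inst/cli/pdc.R audit --children sim/children.csv \
    --visits sim/visits.csv --references sim/references --out-dir audit
```

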