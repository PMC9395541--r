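# wbcplt

Kinetic analysis of acute inflammatory recovery from longitudinal white
blood cell (WBC) and platelet (PLT) counts in hospitalized patients.

## The problem

Trauma, ischemia and infection all trigger an acute inflammatory
response: WBC rises to a peak while PLT dips below its homeostatic
setpoint. Patients who recover well then follow a conserved two-part
program in the WBC–PLT phase plane —

- exponential WBC decay back toward the setpoint,
  `WBC(t) = WBC_set + (WBC_max − WBC_set)·exp(−k_WBC·(t − t_peak))`,
  with `k_WBC` ≈ 0.5–1.0/day (half-life `ln2/k` ≈ 0.7–1.4 days, mean
  leukocyte circulation time `1/k` ≈ 1–2 days), and
- delayed linear PLT growth,
  `PLT(t) = PLT(t_peak + τ) + k_PLT·(t − t_peak − τ)` for
  `t ≥ t_peak + τ`, with a lag `τ` ≈ 2 days, often overshooting the
  setpoint.

Non-dimensionalizing with `w = (WBC − WBC_set)/(WBC_max − WBC_set)`,
`p = (PLT − PLT(t_peak+τ))/(k_PLT/k_WBC)` and
`t* = (t − t_peak)·k_WBC` collapses every such recovery onto one
universal curve, `w = exp(−t*)`, `p = t* − τ·k_WBC`. Deviation from the
cohort's mean favorable trajectory — in **position** (distance in the
normalized plane, counting only WBC-above / PLT-below deviation) and
**direction** (angle between daily change vectors) — stratifies risk of
adverse outcomes (30-day mortality or long stay) out of sample.

The package is for biostatisticians and clinical-informatics researchers
who want to fit this recovery model to hospital laboratory time series,
build reference trajectories, score patients against them, and explore
high-dimensional marker-trajectory clusters. Because such records are
IRB-restricted, a synthetic-cohort generator with known ground truth
(`sim_config()`, `generate_cohort()`) makes every stage testable.

## Worked example

```r
library(wbcplt)

cfg <- sim_config(n_patients = 400, seed = 42)   # cardiac-surgery-like cohort
gen <- generate_cohort(cfg)
cohort <- apply_exclusions(gen$cohort)           # <18 y, <2 d stay, <2 CBCs
print(cohort)
#> Inflammatory-recovery cohort (surgical): 400 patients
#>   mean LOS 9.3 d, 30-day mortality 3.8%

halves <- split_cohort(cohort)                   # earlier half = exploratory
fits <- fit_cohort(modeling_subset(halves$exploratory))
median(fits$c); median(fits$tau)
#> median k_wbc = 0.78 /day (half-life 0.89 d), median tau = 1.75 d
#> median adjusted R2: WBC 0.99, PLT 0.94
```

The fitted decay rates sit inside the physiologic 0.5–1.0/day band and
the PLT lag lands on the configured ~2-day delay (within one 0.25-day
grid step). A single patient's fit prints as:

```r
fit_recovery(cohort$patients[[1]], "surgical")
#> Recovery fit for P0001 (peak WBC at 0.77 d)
#>   WBC: a = 11.96, b = 7.37, k = 0.855 /d (half-life 0.81 d), adjR2 = 0.912 [ok]
#>   PLT: d = 114.9, slope = 22.83 /d, tau = 1.50 d, adjR2 = 0.965 [ok]
```

Risk stratification against the exploratory reference trajectory, scored
out of sample on the validation half at post-event day 4:

```r
ref <- mean_trajectory(halves$exploratory)       # favorable-outcome mean
es  <- risk_scores(halves$exploratory, ref, days = 4)
vs  <- risk_scores(halves$validation,  ref, days = 4)
am  <- assess_risk(vs, es)                       # percentiles from exploratory only
strata_table(am, adverse_outcome(halves$validation), days = 4)[["4"]]
#>            adverse
#> stratum     FALSE TRUE
#>   both_lt50    44    1
#>   mixed       126   15
#>   both_gt80     0    7
#> day-4 adverse rate: 100.0% (both>80th) vs 2.2% (both<50th);
#> RR = 45.0 (95% CI 6.5-312.5)
```

Patients outside the 80th percentile for both position and direction
carry essentially all the adverse outcomes in this synthetic validation
half; patients below the 50th on both are nearly all fine. The whole
chain (simulate → fit → reference → risk → cluster → report) is also
available as one deterministic driver, `run_pipeline(config, out_dir)`,
with a thin command-line wrapper in `inst/scripts/wbcplt.R`.

## Package layout

| Area | Functions |
| --- | --- |
| Synthetic cohorts | `sim_config`, `simulate_recovery_curve`, `simulate_patient`, `generate_cohort`, `split_cohort` |
| Data model & I/O | `patient_record`, `recovery_cohort`, `read_cohort`/`write_cohort`, `resample_12h`, `baseline_mean`, `apply_exclusions`, `find_peak_wbc`, `modeling_subset` |
| Kinetic model | `fit_wbc_decay`, `fit_plt_growth`, `fit_recovery`, `fit_cohort`, `adjusted_r2`, `half_life`, `mean_residence`, `nondimensionalize` |
| Reference trajectory | `good_outcome_mask`, `mean_trajectory`, `direction_bands`, `write_reference`/`read_reference` |
| Risk engine | `position_score`, `direction_score`, `percentile_transform`, `risk_scores`, `assess_risk`, `stratify`, `strata_table`, `relative_risk`, `chi2_2x2`, `sensitivity_specificity` |
| Cluster explorer | `build_feature_matrix`, `filter_markers`, `choose_k_and_cluster`, `cluster_significance` |
| Pipeline | `pipeline_config`, `run_pipeline` |

See the vignette (`vignettes/recovery-kinetics.Rmd`) for the model, the
estimators and their numerical choices, what the synthetic generator
does and does not emulate, and known limitations.
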