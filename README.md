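# gasfx

Synthetic-data pipeline for quantifying how residual bulky rectal gas
perturbs scanned carbon-ion radiotherapy (CIRT) dose in prostate treatments,
and for extracting 2-D radiograph indicators that predict those dose changes.

## Who this is for

Medical-physics researchers studying inter-fractional anatomy changes in
particle therapy. Patient CTs from such studies are rarely shareable, so the
package generates seeded virtual cohorts — paired planning/gas-distended
pelvic CTs with a *known ground-truth deformation field* — and pushes them
through a complete, simplified clinical workflow, every stage of which is
testable against analytic oracles.

## The model at its core

A 12-fraction course (51.6 Gy RBE-weighted, lateral opposed fields at
90°/270°, 6 fractions each, one field per fraction) is planned on the gas-free
CT with robust single-field-uniform-dose (SFUD) optimisation. Physical dose
per voxel is a pencil-beam superposition

> D(v) = Σ_spots w_s · DDD(WEPL(v)) · G(σ; lateral offset),

with WEPL the water-equivalent path length from HU→stopping-power
calibration. Biological weighting follows the modified microdosimetric
kinetic model (MKM, HSG cell line: α₀ = 0.1720 Gy⁻¹, β = 0.0615 Gy⁻²):

> α(v) = α₀ + β·z₁D*(v),  ln S = −α D − β D²,
> D_RBE = [−α_ref + √(α_ref² − 4 β_ref ln S)] / (2 β_ref).

The plan is recalculated with fixed parameters on the gas CT, the resulting
per-fraction doses are warped back to the planning frame through the
(ground-truth or demons-estimated) displacement vector field, and 13 summed
dose distributions are composed for k = 0…12 gas-affected fractions
(gas-90° first, extra 90° fraction on odd k). Changes in CTV Dmin and
D99.5% (percent) and rectum/rectal-wall V95% and V80% (cm³) versus the
initial plan are summarised at the cohort 75th percentile with 1/2-cm³
threshold crossings, tested with exact Wilcoxon signed-rank statistics, and
correlated (Pearson) with three DRR gas indicators measured on oblique
35°/325° projections: `DRR_gas_SI`, `DRR_gas_side` and their product
`DRR_gas_area`.

## Worked example

```r
library(gasfx)

ph  <- generate_phantom(phantom_spec(), seed = 7)
ins <- insert_gas(ph$ct, ph$structures, gas_spec(target_volume_cm3 = 15), seed = 8)
ins$achieved_volume_cm3
#> [1] 15

spr  <- hu_to_spr(ph$ct)
plan <- optimize_sfud(spr, ph$structures)          # ~15 s
doses <- plan_field_doses(plan, spr)
total <- dose_grid(6 * doses[["90"]]$rbe$dose + 6 * doses[["270"]]$rbe$dose,
                   spr$spacing, spr$origin, "rbe_weighted", "total")
validate_constraints(total, ph$structures)
#>     structure metric limit direction measured pass
#> 1         ctv   dmin 47.90         > 48.85690 TRUE
#> 2         ctv  d99_5 49.02         > 50.62712 TRUE
#> 3      rectum    v95  0.80         <  0.01600 TRUE
#> 4      rectum    v80  4.10         <  0.40800 TRUE
#> 5 rectal_wall    v95  0.80         <  0.01600 TRUE
#> 6 rectal_wall    v80  4.10         <  0.40000 TRUE
```

All four planning constraints hold on the baseline plan: the CTV minimum dose
clears 47.90 Gy and the rectum receives less than 0.8 cm³ above 95% of the
prescription. The full cohort (about 8 minutes on one core):

```r
run <- run_cohort(run_config(cohort_size = 18, seed = 1))
summary(run)
#> Correlation coefficients (rows: DVH parameter changes at k = 12)
#>   ctv_dmin               0.445   0.486   0.189   0.564*  0.461
#>   rectum_v95             0.802   0.676   0.442   0.782   0.804*
#>   rectum_v80             0.801   0.761   0.545   0.841   0.848*
#>   ...
#> MKM->LEM conversion factor at 4.30 Gy/fx: 1.0789
```

Rectum and rectal-wall dose changes grow monotonically with the number of
gas-affected fractions, and `DRR_gas_area` — the size of the projected gas
shadow overlapping the target — carries the strongest correlation with the
rectum dose change (r ≈ 0.80 for ΔV95% at k = 12 under seed 1), which is the
package's in-silico version of "the radiograph predicts the dosimetric
penalty". `write_run_tables(run, dir)` exports the delta, indicator, test and
correlation tables as CSV.

## Layout

- `R/phantom.R` — phantom + gas-pocket generator (the synthetic-data module)
- `R/dose_engine.R`, `R/plan.R` — SPR, WEPL, Bragg-curve fixtures, MKM, SFUD
- `R/registration.R` — rigid bone match, demons DIR, dose warping, Dice/Hausdorff
- `R/fractions.R`, `R/dvh.R` — scenario composition and DVH analysis
- `R/drr.R` — oblique projections and gas indicators
- `R/stats.R` — signed-rank, correlations, MKM→LEM interpolation
- `R/pipeline.R`, `R/io.R` — cohort orchestration, NIfTI/CSV/JSON/YAML IO
- `vignettes/gas-dose-simulation.Rmd` — methods, assumptions, limitations
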