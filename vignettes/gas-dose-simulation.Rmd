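---
title: "Simulating rectal-gas-induced dose changes in carbon-ion therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating rectal-gas-induced dose changes in carbon-ion therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gasfx)
```

## The problem

Scanned carbon-ion beams stop at a depth set by the integrated stopping power
along their path. A pocket of rectal gas that appears between planning and
treatment removes several centimetres of water-equivalent material from the
lateral beam path of a prostate treatment and simultaneously distends the
rectum, moving the rectal wall relative to the planned dose gradients. Clinics
therefore often remove bulky gas before each fraction, an uncomfortable and
time-consuming procedure. The question this package addresses in silico is:
*how many of the 12 fractions can be delivered with bulky gas before the dose
to the target, rectum and rectal wall deviates meaningfully from the plan, and
can that deviation be predicted from the 2-D setup radiographs already
acquired for positioning?*

Because patient CTs cannot be shared, the package is built around a seeded
synthetic cohort. Every stage of the clinical workflow is reimplemented in a
simplified, analytically checkable form:

1. **Phantom generation** (`generate_phantom()`, `insert_gas()`): paired
   planning/gas CTs with a known ground-truth deformation.
2. **Dose engine** (`optimize_sfud()`, `plan_field_doses()`,
   `recalc_plan()`): scanned-carbon pencil-beam dose with biological
   weighting by the modified microdosimetric kinetic model (MKM).
3. **Registration** (`rigid_bone_match()`, `deformable_register()`,
   `warp_dose()`): bone-match rigid alignment, demons-style deformable
   registration with a structure term, and pull-back dose warping.
4. **Fraction scenarios** (`build_schedule()`, `compose_scenarios()`):
   13 summed dose distributions for 0 to 12 gas-affected fractions.
5. **Evaluation** (`dvh_metrics()`, `delta_metrics()`,
   `cohort_threshold_crossing()`, `project_drr()`, `compute_indicators()`,
   `build_correlation_table()`, `wilcoxon_signed_rank()`).

`run_cohort()` chains all stages for a seeded cohort of 18 virtual patients.

## The phantom and what it does (and does not) emulate

The pelvic phantom is a 64 x 64 x 56 grid of 2-mm voxels: an elliptical soft
tissue body, an ellipsoidal prostate plus a smaller superior-posterior
ellipsoid standing in for the seminal-vesicle base (together the CTV), a
cylindrical rectum abutting the prostate posteriorly, femoral heads, a pubic
bar and a sacrum in bone HU, and Gaussian HU noise (SD 15). Contours follow
the clinical derivation rules: the rectum is cropped to 14 mm beyond the CTV
ends, the rectal wall is the inner 2-mm ring, and the PTV adds 5-mm margins
to the right, left and anterior sides only (the direction set is clinical
practice; the magnitudes are this package's choice, as only the directions
are prescribed in the protocol it mirrors).

Gas insertion is the part the whole study hinges on, so it is constructed to
be exactly self-consistent. The deformation is an analytic radial push away
from the rectal axis: the in-plane profile rises linearly to the rectal
radius and decays as a Gaussian beyond it, with a Gaussian envelope along the
rectum centred on the pocket; the peak distension is 3.5 mm. Because the map
`T(x) = x + u(x)` is analytic, its inverse is obtained by fixed-point
iteration and the gas CT is the planning CT pulled back through `T`, with the
pocket painted at gas HU (-1000). The pocket itself is an ellipsoid carved
inside the distended rectum; its axial half-length is solved by bisection so
the carved volume matches the requested volume, and requests beyond the
rectum's deformable capacity are capped with a warning. The returned
displacement field is the exact `u` used, which gives the registration and
warping stages a genuine ground truth: warping the gas-CT rectum back through
the true field reproduces the planning rectum with Dice above 0.99.

Cohort-scale gas volumes are drawn from a gamma distribution with mean
17.54 cm^3 and SD 11.10 cm^3, the bulky-gas statistics the study conditions
specify; pocket locations are superior-weighted (75/20/5 superior/middle/
inferior), matching the observation that bulky gas sits mostly cranial to the
target. Session-to-session variability options (volume SD 2.9 cm^3, position
jitter within 5 mm) are available through `jitter_gas_spec()`.

What the phantom does **not** emulate: realistic CT texture, stool, rectal
curvature, haustral folds, bladder filling, or inter-patient variation beyond
jittered organ sizes and centres. Passing tests on this cohort demonstrate
that the *pipeline* behaves correctly and that the qualitative findings
(monotone organ-dose degradation with gas fractions, positive correlation
between projected gas extent and dose change) emerge from the physics; they
do not validate patient-specific magnitudes.

## Dose engine

CT numbers convert to stopping-power ratios through a shipped piecewise-linear
calibration anchored at (0 HU, 1.0). Water-equivalent depth is accumulated
along each lateral ray with a midpoint convention. Depth-dose curves are
analytic Bragg-curve fixtures (rising plateau, sigmoid distal cut-off,
Gaussian peak whose width grows with range) together with a z1D* curve — the
dose-weighted mean specific energy per domain — rising sigmoidally across the
peak, emulating the increase of linear energy transfer toward and beyond the
Bragg peak. These fixtures stand in for a commercial beam model; they keep
the two properties the analysis depends on, a sharp distal edge whose
position responds to upstream density and a biological weighting that grows
with depth.

Biological weighting follows the modified MKM with HSG-cell parameters
alpha0 = 0.1720 /Gy and beta = 0.0615 /Gy^2: per voxel
`alpha = alpha0 + beta * z1D*`, `ln S = -(alpha D + beta D^2)`, and the
RBE-weighted dose is the reference-radiation dose with equal survival. The
reference LQ parameters default to `(alpha0, beta)` — the zero-LET limit of
the same model — so the weighting is exactly invertible and
`D_rbe = D_phys` wherever `z1D* = 0`. The printed nucleus/domain radii
(0.320/3.900 micron pairing as published, which is swapped relative to
common modified-MKM usage) are carried as metadata only, with the standard
assignment; the fixtures encode z1D* directly, so nothing downstream depends
on them.

Planning uses one field per fraction from 90 and 270 degrees, six fractions
each, 51.6 Gy (RBE) in 12 fractions. Each field is optimised independently to
deliver a uniform 4.3 Gy (RBE) to the PTV (single-field uniform dose). The
optimiser is a projected L-BFGS-B on non-negative spot weights minimising a
softmax-smoothed worst case over five isocentre-shift scenarios (nominal and
2 mm anterior-posterior/superior-inferior), with quadratic penalties for PTV
under/overdose and rectum/wall dose above 80% of the fraction dose. Because
RBE weighting varies with depth, the physical target is tilted per voxel by
inverting the MKM relation at the current z1D* estimate and refined once.
After per-field normalisation to a median of 4.3 Gy (RBE), both fields are
scaled together, if needed, until the summed CTV D99.5% clears its planning
constraint with a 1.5% margin — the renormalisation-to-coverage step a
planner would apply. Defaults: 5-mm spot pitch, 4-mm energy-layer step, 4-mm
lateral sigma, 160 + 80 iterations, about 1000 spots and 2400 sampled voxels
per field; the optimisation is deterministic (no random numbers are drawn)
and takes roughly 15 s per patient on one CPU.

The per-field uniformity property is assessed on a uniform-water box fixture
with finer settings (4-mm pitch, 3-mm layers, 6-mm placement margin, nominal
scenario only, 600 iterations), where the optimiser reaches about 2%
(max - min)/prescription across the target. On the pelvic phantom the same
5% band is not geometrically attainable: the CTV Dmin constraint pins the
posterior dose edge at 92.8% of prescription against an abutting rectum, so
plan quality there is judged by the clinical constraint set instead (CTV
Dmin > 47.90 Gy, D99.5% > 49.02 Gy, rectum and wall V95% < 0.80 cm^3 and
V80% < 4.10 cm^3), which the default phantom plans satisfy.

Recalculation on the gas CT keeps every spot, weight and energy fixed and
changes only the traversed stopping power — gas is *not* overridden with
water there, because the point is to simulate what the delivered fraction
would have done (`override_gas_with_water()` exists for the planning side).

## Registration and dose accumulation

Rigid bone matching optimises 6 degrees of freedom by Nelder-Mead on the
mean squared HU difference over bone-threshold voxels, initialised at the
bone-centroid offset; it recovers 10-mm shifts to better than 0.1 mm on
phantoms. Deformable registration is a two-level demons scheme whose force
combines an intensity channel (HU/400) with a signed-distance channel per
supplied structure pair (weights 0.3 and 1.0); the displacement update is
capped at 0.45 voxel per iteration and Gaussian-smoothed (sigma 1.2 voxels).
The structure term carries regions without intensity correspondence — newly
appeared gas has no counterpart on the planning CT. Residuals are tracked and
an increase over a level raises an error rather than returning a silently
bad field. The field convention is fixed: the DVF lives on the planning grid
and maps planning points to gas-CT points, so dose warping is pull-back
sampling `warped(v) = dose(v + DVF(v))` with trilinear interpolation and
zero outside the field — integer-voxel translations are exact by
construction. A first-class bypass returns the generator's exact field, so
cohort dose conclusions can be decoupled from registration quality; the
default cohort run uses this mode, and registration accuracy is verified
separately (mean field error about 1 mm, warped-rectum Dice above 0.99 in
estimate mode). The pipeline's rigid step defaults to the identity because
the generator introduces no rigid offset and bone barely moves under the gas
deformation model.

## Fractions, DVH and DRR indicators

Gas-affected fractions are assigned gas90-first with the extra 90-degree
fraction on odd counts: `n_gas90 = ceiling(k/2)`, `n_gas270 = floor(k/2)`.
Scenario `k` is the integer combination of the four per-fraction RBE-weighted
dose grids; treating RBE-weighted fraction doses as additive is the planning
system convention adopted here, noted as an approximation. Thirteen
distributions result, the baseline `k = 0` included.

DVH quantities use linear interpolation between order statistics (quantile
type 7) for Dy% — Dmin is the raw minimum voxel dose — and inclusive
thresholds for Vx% in absolute cm^3; both choices are deliberate
(alternatives exist, none is prescribed) and both are frozen by brute-force
oracle tests. Target deltas are reported in percent of baseline, organ deltas
in absolute cm^3, and cohort summaries use the 75th percentile with strict
(>) threshold crossing at 1 and 2 cm^3.

DRRs are parallel-ray line integrals of `(HU + 1000)/1000` about the
superior-inferior axis at the oblique imager angles 35 and 325 degrees
(parallel rather than divergent geometry keeps silhouettes analytic; 1-mm
pixels, 2-mm ray steps). The projected gas region is the HU window -1200 to
-120 inside the gas-CT rectum. Three indicators are measured per angle and
averaged: the SI extent of the gas shadow within the projected PTV's SI span
(`DRR_gas_SI`); the maximum transverse distance by which gas pixels inside
the PTV shadow extend outside the rectum shadow (`DRR_gas_side`); and their
product (`DRR_gas_area`), an identity that holds exactly by construction.
The SI indicator is read as an overlap extent, not a gap distance — a gap
reading would score large pockets as zero and could not correlate positively
with dose change; max-extent endpoints are the default. The same HU window
doubles as the volumetric gas definition, a reuse this package makes
explicit rather than an assertion about the source system.

## Statistics

Paired scenario-versus-baseline comparisons use a two-sided Wilcoxon
signed-rank test: zeros dropped, exact enumeration of all 2^n sign patterns
up to n = 12, normal approximation with tie correction beyond, no
multiple-testing correction (raw per-k p-values). Differences below 1 nGy are
treated as ties in the pipeline to keep floating-point noise out of the
test. Correlation analysis at k = 12 relates the six DVH deltas to five
indicators (rectal volume change, gas volume change, and the three DRR
indicators, angle-averaged) with Pearson coefficients, flagging the strongest
indicator per row; constant columns are reported as undefined rather than 0.
The scalar MKM-to-LEM conversion is linear interpolation between the
published anchors (4.20 Gy, 1.09) and (4.38 Gy, 1.07) — about 1.08 at the
4.3 Gy fraction dose used here — with no extrapolation.

## Numerical choices and degenerate inputs

* Masks are inclusive of boundary voxels; volumes are voxel count times
  voxel volume; all physical distances derive from the stored spacing.
* Erosion/dilation use physical-ball structuring elements; a wall thinner
  than twice the ring thickness degrades to the whole structure with a
  warning; zero thickness gives an empty wall.
* PTV margins quantise to whole voxels (`round(margin/spacing)`).
* Both-empty masks have Dice 1.0 by definition; Hausdorff requires nonempty
  masks and uses surface-voxel centres.
* Out-of-volume samples: zero for dose warping (out-of-field means no dose),
  border-replication inside the demons iterations (a displaced sample must
  not fabricate a residual), air for rigid matching.
* The divergence guard in the demons scheme and the constraint report in the
  optimiser fail loudly; neither returns a silently degraded result.

## Problem sizes and determinism

The shipped defaults — 64 x 64 x 56 voxel phantoms, about 1000 spots and
2400 sampled voxels per field, 18 patients — were chosen so a full cohort
run completes in roughly ten minutes on a single core while every structure
spans enough voxels for stable DVH statistics. Every random draw flows from
one master seed (per-patient seeds are derived as `seed * 1000 + patient`),
and regenerating with the same configuration and seed reproduces every
deterministic output bit for bit.

## A short example

```{r example, eval = FALSE}
library(gasfx)

ph  <- generate_phantom(phantom_spec(), seed = 7)
ins <- insert_gas(ph$ct, ph$structures, gas_spec(target_volume_cm3 = 15), seed = 8)
ins$achieved_volume_cm3

spr  <- hu_to_spr(ph$ct)
plan <- optimize_sfud(spr, ph$structures)
doses  <- plan_field_doses(plan, spr)
gas    <- recalc_plan(plan, hu_to_spr(ins$gasct))
g90  <- warp_dose(gas[["90"]]$rbe,  ins$dvf)
g270 <- warp_dose(gas[["270"]]$rbe, ins$dvf)
scen <- compose_scenarios(doses[["90"]]$rbe, doses[["270"]]$rbe, g90, g270)
delta_metrics(scen, ph$structures)

# or, end to end:
run <- run_cohort(run_config(cohort_size = 18, seed = 1))
summary(run)
```

## Known limitations

Single-Gaussian, depth-independent lateral penumbra; no nuclear
fragmentation tail or multiple-Coulomb-scattering growth; analytic beam-model
fixtures rather than a track-structure calculation; parallel-beam DRRs; one
gas CT per patient reused across gas fractions (the reproducibility options
only jitter the generator); no DICOM interfaces. Cohort-level numbers from
this synthetic pipeline characterise the method, not any patient population.
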