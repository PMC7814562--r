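# phytopet

Quantitative analysis of radiotracer transport in plants imaged by dynamic
PET/CT, together with a synthetic 4D phantom that makes every analysis stage
testable against exact ground truth.

## The problem

Clinical PET/CT scanners can image several whole plants simultaneously and
continuously for days. With a long-lived tracer such as ²²Na (half-life
2.605 y) added to the root solution, the dynamic image series records sodium
moving from the root-side pool (beaker solution + roots) into the shoot —
and how that transport responds to nutrient status, cation-channel
inhibitors (e.g. BaCl₂) and the light/dark cycle. This package is for plant
physiologists and imaging scientists who need to turn such a 4D series into
defensible numbers:

* **ROIs**: rectangular prisms in PET voxel space, built from region heights
  measured on the CT image and the plants' lateral isolation-cylinder
  bounds, with a boundary convention that guarantees regions partition the
  plant column.
* **TACs and ratios**: per-region time-activity curves, decay correction
  (`A·2^((t−t_ref)/T½)`), and per-plant normalization `R_region(t) =
  A_region(t) / Σ_regions A(t)`.
* **Rates and kinetics**: rate of change by first central differences and
  the per-frame uptake-rate estimate for the two-pool model
  `dA_leaf/dt = k(t)·A_pool`:

  `k̂(t) = (dR_leaf/dt) / R_root(t)`.

* **Diurnal statistics**: a circular-shift permutation test for a light/dark
  difference in uptake rate (exhaustive shifts of the light mask; preserves
  autocorrelation; trend-robust by default).
* **QC and validation**: whole-grouping activity totals vs. the known
  administered dose with and without attenuation correction, and drift
  detection on a constant reference source.
* **Synthetic phantom**: four simultaneously scanned plant groupings
  (high/low nutrient × with/without inhibitor) with exact closed-form
  kinetics `A_leaf(t) = A_total·(1 − e^(−∫k))`, physical decay, lateral
  attenuation, and Poisson counting noise — with full ground-truth
  bookkeeping.

Volumes are NIfTI-1 (via RNifti); schedules, ROIs and results use JSON/CSV
sidecars.

## Worked example

Simulate the default experiment (64×64×48 PET grid, 72 one-hour frames,
12 h light / 8 h dark, administered doses 2.25/2.09/2.00/2.03 MBq) and run
the full analysis:

```r
library(phytopet)
spec <- default_phantom_spec(seed = 42)
ds   <- generate_dataset(spec)
ds
#> <synthetic_dataset> 64 x 64 x 48 voxels x 72 frames, 4 groupings, doses 2.25/2.09/2/2.03 MBq

res <- run_pipeline(run_config(out_dir = "demo", spec = spec, seed = 42))

res$diurnal$low_noBa
#> <diurnal_result> D = 0.00678 /h (light 0.01228, dark 0.005503), p = 0.01389 over 72 shifts
```

The low-nutrient plants' leaf uptake rate is about 0.0122 per hour in light
versus 0.0055 in dark; the circular-shift test rejects a non-diurnal null at
p = 1/72 (the smallest attainable p over 72 shifts).

```r
res$ac_validation
#>    plant_id ground_truth_MBq est_with_AC_MBq est_without_AC_MBq rel_err_with_AC rel_err_without_AC
#> 1 high_noBa             2.25        2.241849           2.172209    -0.003622818        -0.03457366
#> 2   high_Ba             2.09        2.079818           1.810224    -0.004871959        -0.13386388
#> 3  low_noBa             2.00        2.011412           1.902625     0.005706133        -0.04868759
#> 4    low_Ba             2.03        2.017577           1.944716    -0.006119705        -0.04201179
```

With attenuation correction the whole-grouping totals recover the
administered doses to well under 1%; without it every grouping is
underestimated (3–13% here, most where the tracer still sits in the
attenuating solution).

```r
res$drift
#> <drift_report> max relative deviation 0.02912 (threshold 0.05): PASS

vapply(res$ratios, function(r) r$leaf$R[72], numeric(1))
#> high_noBa   high_Ba  low_noBa    low_Ba
#>     0.554     0.336     0.723     0.475
```

The final-frame leaf ratios show both designed treatment effects: low
nutrient > high nutrient within each inhibitor arm, and no-inhibitor >
inhibitor within each nutrient arm. `run_pipeline()` also writes the curve
CSVs, diurnal/drift JSON, the attenuation-correction table, anticipation
scan and per-plant ratio/rate figure panels (dark periods shaded) under
`out_dir`.

To analyse saved data instead of a simulation, point `run_config()` at a 4D
NIfTI file plus its frame-schedule and ROI JSON sidecars (`pet_path =`,
`schedule_path =`, `rois_path =`, `light =`).

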