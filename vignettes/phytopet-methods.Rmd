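---
title: "Quantifying sodium transport in plants from dynamic PET: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sodium transport in plants from dynamic PET: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytopet)
```

## The measurement problem

A clinical PET/CT scanner can image several whole plants simultaneously and
continuously for days. With a long-lived positron emitter such as sodium-22
(half-life 2.605 years) added to the root solution, the reconstructed dynamic
series shows tracer moving from the root-side pool (beaker solution plus
roots) into the shoot. The quantities of interest are simple but must be
extracted carefully:

* per-region **time-activity curves** (TACs) — activity summed over a region
  of interest per one-hour frame;
* the **relative radioactivity** of each region — the region's activity
  divided by that plant's total at the same frame, which cancels dose
  differences between plants and residual physical decay;
* the **rate of change** of these ratios, computed by first central
  differences, in which treatment effects (nutrient status, a cation-channel
  inhibitor such as BaCl~2~) and the light/dark rhythm of uptake are visible;
* validation quantities: whole-grouping activity totals compared against the
  known administered dose (with and without attenuation correction), and the
  flatness of a constant reference source (scanner drift).

The real scanner data behind such an experiment is not generally available,
so the package pairs the analysis pipeline with a synthetic 4D phantom whose
ground truth is known exactly. Every analysis stage is tested against that
phantom; the phantom is itself first-class, tested code.

## The kinetic model

Each plant grouping is modelled as two well-mixed pools. The root-side pool
(solution + roots, which the root ROI observes jointly because the prism
includes the beaker) feeds the shoot pool irreversibly:

$$\frac{dA_\mathrm{leaf}}{dt} = k(t)\,A_\mathrm{pool}(t), \qquad
A_\mathrm{pool} = A_\mathrm{total} - A_\mathrm{leaf}, \qquad
A_\mathrm{leaf}(0) = 0,$$

with the uptake-rate coefficient

$$k(t) = k_\mathrm{base}\, f_\mathrm{nutrient}\, f_\mathrm{inhibitor}\,
\bigl(1 \pm a_\mathrm{diurnal}\bigr),$$

the sign chosen by whether the *anticipated* clock $t + \delta$
(`phase_advance` $\delta \ge 0$) falls in a light interval of the periodic
schedule. Because $k$ is piecewise constant, the solution is exact:

$$A_\mathrm{leaf}(t) = A_\mathrm{total}\left(1 - e^{-\int_0^t k(s)\,ds}\right),$$

with the integral accumulated segment by segment over light/dark intervals.
No numerical ODE solver is involved in the simulator; an adaptive solver
serves only as an independent oracle in the test suite (agreement is required
to below 1e-8 relative over random parameter draws).

Amounts are *undecayed* in the compartment series, so
$A_\mathrm{pool}+A_\mathrm{leaf}=A_\mathrm{total}$ holds exactly at every
frame; physical decay (factor $2^{-t/T_{1/2}}$ with $T_{1/2}$ = 2.605 y,
one year taken as 8766 h) is applied at render time, per frame midpoint.

### Default parameters

The phantom defaults encode the study conditions: four groupings scanned
simultaneously for 72 one-hour frames under a 12 h light / 8 h dark cycle
(kept verbatim as a 20-h cycle; nothing assumes a 24-h day), with
administered doses 2.25, 2.09, 2.00, 2.03 MBq in scanner order high-nutrient
without inhibitor, high with, low without, low with. The treatment factors —
`f_nutrient` 1.0 (high) / 1.6 (low), `f_inhibitor` 1.0 (without) / 0.5
(with), `a_diurnal` 0.4 around `k_base` 0.01/h — are calibration choices of
this package producing curve shapes with the qualitative features reported
for such experiments (low-nutrient > high-nutrient uptake; suppression under
the inhibitor; markedly faster uptake in light); they are configuration, not
measured values. `phase_advance` defaults to 0; anticipation is explored
explicitly via `anticipation_scan()` or by setting it in the spec.

## From scene to image

`build_geometry()` voxelizes each grouping as a vertical stack — a
solution/root cylinder (the beaker), a thin stem column, a leaf-canopy
cylinder — at laterally disjoint positions, plus a small constant-activity
reference box. The label volume is validated to be a partition (one code per
voxel). `render_frames()` spreads each compartment's decayed activity
uniformly over its voxels; the stem renders empty by default
(`stem_fraction = 0`), mirroring analyses that quantify roots and leaves
only. Noiseless frame totals therefore equal the decayed administered totals
exactly, a conservation law the tests check to 1e-10.

Attenuation is deliberately simple: each voxel's photons are assumed to
escape laterally along x, and `build_attenuation_map()` computes
$e^{-\mu\,d}$ with $d$ the water-equivalent thickness crossed to the nearer
lateral face (attenuating material: the solution/root compartment;
$\mu = 0.0096$/mm, water at 511 keV). An attenuating voxel contributes its
full x-width when crossed and half when it is the source voxel. This
validates the *correction arithmetic* — the point of the attenuation
comparison — not scanner physics; line-of-response modelling, scatter and
randoms are out of scope.

Counting noise replaces each voxel-frame activity $v$ by
$\mathrm{Poisson}(v\,s\,\Delta t)/(s\,\Delta t)$ with a single scalar
sensitivity $s$ (counts per MBq·h per voxel; default 1e4). Because ROI
counts sum to $\mathrm{Poisson}(A_\mathrm{ROI}\, s\, \Delta t)$, the noise
regime of a TAC depends only on activity, not on grid size — which is why
the test suite can run on reduced grids without changing the statistics.
Both reconstructions of a simulated scan share one noise realization: the
uncorrected image is the noisy attenuated data, the corrected image divides
the same data by the true attenuation map.

## ROI construction and TAC analysis

Region boundaries are measured as heights (mm above the beaker bottom) on
the CT image and converted to PET slice indices using the voxel dimensions.
The package fixes a convention the conversion needs but measurements do not
supply: voxel $i$ covers the half-open interval
$[\,c_i - s/2,\; c_i + s/2\,)$ around its center, with boundary positions
assigned to the higher index. A height interval $[z_0, z_1)$ then maps to
slices $\mathrm{idx}(z_0) \ldots \mathrm{idx}(z_1)-1$, so abutting regions
partition the plant column with no double-counted voxel — a requirement for
ratios that must sum to 1. Prisms of one plant share their lateral bounds
(the isolation-cylinder bounding box) exactly. Voxel indices are zero-based
throughout the public API, matching NIfTI voxel coordinates.

TACs are decay-corrected to administration time (a ≤ 0.22% effect for
sodium-22 over 72 h, applied for correctness and required by the drift
check), normalized per plant, and differentiated by first central
differences; the two endpoint frames use one-sided differences and are
tagged and excluded from downstream statistics. For the two-pool model the
per-frame uptake rate is recoverable algebraically:

$$\hat k(t) = \frac{dR_\mathrm{leaf}/dt}{R_\mathrm{root}(t)},$$

evaluated at interior frames with $R_\mathrm{root} > \varepsilon$
(default 0.05) to avoid division blow-up as the pool empties. The central
difference of the exponential solution gives
$\hat k = k\,\sinh(kh)/(kh)$ at spacing $h$ = 1 h, a relative bias of
$(kh)^2/6 \approx 2\times10^{-5}$ at $k = 0.01$/h — far below the 1%
recovery tolerance the tests impose.

## The diurnal test

Whether plants take up more tracer in light than in dark is tested on the
leaf rate curve with a circular-shift permutation null: the contrast
$D = \overline{dR/dt}_\mathrm{light} - \overline{dR/dt}_\mathrm{dark}$ is
recomputed for every circular shift of the light mask (all shifts enumerated
exhaustively — no sampling, no RNG), and the two-sided p-value is the
fraction of shifts whose $|D_s|$ reaches $|D_\mathrm{obs}|$. Shifting the
mask rather than permuting frame labels preserves the serial correlation of
both the series and the mask; the identity shift counts itself, so
$p \ge 1/n$.

One subtlety matters. The rate series carries a slow deterministic decline —
the root pool empties, so $dR_\mathrm{leaf}/dt$ shrinks over the scan —
and a trend is not circularly stationary. Tested raw, the null becomes
severely conservative (no rejections where ~5% are expected). The statistic
is therefore computed on the residuals of a cubic polynomial trend fit
(mask-independent, so the identity-shift tie is preserved); the reported
contrast `D` and the light/dark means stay on the raw, interpretable scale,
and `detrend = FALSE` restores the raw statistic. With detrending the test
is calibrated (measured Type-I rate ≈ 4–5% at the 5% level over null
phantoms) and retains essentially full power at `a_diurnal = 0.4` under
moderate counting noise.

Anticipation of the light transition is reported descriptively, not tested:
`anticipation_scan()` recomputes $D$ with the mask advanced by
0–4 h and reports the lead time maximizing the contrast.

## Validation stages

**Attenuation correction.** At the final frame, the whole-grouping prism
total (beaker and solution included), decay-corrected to $t=0$, is compared
with the administered dose. With the exact map the corrected estimate is
essentially unbiased (noiseless error < 1%); without correction the totals
strictly underestimate the truth for every grouping. A real scanner's
corrected estimates sit slightly *above* truth for calibration reasons; an
exact-map phantom cannot reproduce that bias, so near-equality with
correction plus strict underestimation without it is the reproducible core
being validated.

**Reference drift.** The decay-corrected TAC of the constant reference
source should be flat; the QC reports
$\max_t |A(t)-\bar A|/\bar A$ against a 5% threshold. A 10% linear
sensitivity decline produces a deviation of $0.05/0.95 \approx 0.053$ and is
flagged; a clean Poisson reference with ~1e4 expected counts per frame stays
within threshold in ≥ 95% of runs.

## Numerical and design choices

* **Frame timestamps** are frame midpoints (start + duration/2); the ratio
  cancels decay exactly frame-by-frame regardless.
* **Noiseless correction is exact by construction**: in noiseless mode the
  corrected image *is* the rendered truth, because multiplying and dividing
  by the same IEEE factors is not bit-stable in general and exactness is the
  property being relied on downstream.
* **The solution and roots are one pool.** The root ROI includes the beaker,
  so the observable signal is the merged pool; a finer solution→root→shoot
  chain would not be identifiable from the prism TACs.
* **Degenerate inputs error loudly**: empty prisms after conversion,
  out-of-extent bounds, frame-count mismatches, zero plant totals (with the
  frame index), masks with an empty light or dark category.
* **Problem sizes in the tests.** Statistical properties (estimator
  recovery, test calibration and power, drift pass rates) are exercised on a
  24×24×24 grid with the full 72-frame schedule; since ROI counting
  statistics depend only on activity × sensitivity, the reduced grid leaves
  the noise regime unchanged. Conservation and geometry checks run on the
  full 64×64×48 grid.

## What the phantom does and does not show

The phantom emulates the *structure* of the experiment — four treatment
groupings, a constant reference, decay, attenuation, Poisson counting noise,
diurnally modulated first-order transport — so it can prove the analysis
correct: conversions are exact, sums match brute force, estimators recover
known rates, tests are calibrated. It does not emulate partial-volume
spill-over between thin plant structures, scatter and randoms, scanner
calibration bias, reconstruction artifacts, plant growth during the scan, or
biological variability between plants within a grouping. Passing tests
therefore certify the pipeline's arithmetic and statistics, not the
biological interpretation of any particular scanner dataset.
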