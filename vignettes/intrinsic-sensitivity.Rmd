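---
title: "Intrinsic detector sensitivity analysis: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intrinsic detector sensitivity analysis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doseqa)
```

## The question the package answers

Patient-specific quality assurance of VMAT deliveries usually compares a
*measurement* to a *treatment-planning prediction*. A failed (or passed)
gamma analysis then confounds several things at once: the detector's own
spatial resolution and noise, the prediction model, and the interpolation
applied to put two differently sampled dose matrices on a common grid.
The *intrinsic sensitivity* design removes the prediction from the loop:
a delivery with a deliberately introduced machine error is measured, and
that measurement is compared against the *measured* baseline (no-error,
"NE") delivery of the same plan on the same detector. Whatever
detectability remains is a property of the detector and of the gamma
criteria alone — an upper bound on what any QA chain built on that
detector can resolve.

`doseqa` re-creates this design entirely in software so that its
structural conclusions can be reproduced, probed and extended without
access to a linac:

1. **Synthetic plans** (`generate_patient_plan()`): two-arc lung-SBRT-like
   VMAT plans on a 40-leaf-pair MLC (5 mm leaf width at isocenter).
2. **Delivery errors** (`apply_error()`): collimator-angle offsets
   (degrees), MLC field-size changes and MLC bank shifts (mm), at the
   signed magnitudes 1, 2 and 5.
3. **Dose rendering** (`render_arc_dose()`, `render_composite_dose()`):
   a planar dose surrogate per arc or per plan.
4. **Virtual detectors** (`measure()`): a sparse cylindrical diode array
   (1386 diodes, 5 mm export grid) and a dense flat-panel imager
   (1024×1024 pixels at 0.4 mm, 0.255 mm export grid), with multiplicative
   measurement noise.
5. **Gamma analysis** (`gamma_index()`): global dose-difference /
   distance-to-agreement comparison with a 10% low-dose threshold,
   summarised as the gamma pass rate (GPR, % of assessed points with
   γ ≤ 1) and gamma mean value (GMV).
6. **Study orchestration** (`run_study()`): cohort × error grid ×
   detector × criteria × resolution, with strict below-baseline error
   detection calls and mean ± SD aggregation.

## The dose model

The delivered dose is represented by a planar 2D surrogate. Each control
point contributes the union over leaf pairs of the rectangle
`[leaf_left, leaf_right] × leaf row`, convolved with an isotropic Gaussian
penumbra kernel (σ = 2.5 mm by default, giving a realistic ≈6 mm 80–20%
penumbra), rotated by the control point's collimator angle about the
isocenter, and accumulated with its monitor-unit weight. Because the
kernel is isotropic, convolution and rotation commute; the implementation
therefore evaluates the *analytically* convolved aperture — a product of
error-function edge profiles, separable in the collimator frame, one
matrix product per control point — and rotates the smooth result by
bilinear resampling. At collimator 0° the rendered field equals the
closed-form erf profile to floating-point accuracy, which the test suite
uses as its rendering oracle.

Two modelling conventions matter:

* **Closed leaf pairs do not irradiate.** A pair whose gap is at the
  mechanical minimum (0.5 mm) is treated as parked/abutted and contributes
  no dose. A literal 0.5 mm open sliver convolved with a 2.5 mm kernel
  would otherwise add a spurious ridge of ≈8% of an open field along the
  bank midline, which no real MLC (whose closed tips sit under the jaw)
  produces.
* **Relative dose.** Every rendered distribution is normalised to maximum
  1; the gamma normalisation dose is the maximum of the *reference*
  (baseline) measurement, so all comparisons are in the global,
  reference-normalised convention.

This surrogate deliberately omits the physics it does not need: no 3D
dose, no gantry-resolved scoring, no MLC transmission or tongue-and-groove,
no cylindrical phantom attenuation, no portal-image dose calibration. The
intrinsic-sensitivity design compares like with like (same detector, same
geometry, same processing on both sides), so the studied effects —
resolution, DD% vs DTA, interpolation — survive the simplification.

## The error model

* `COLLIMATOR ± m°` adds `m` to every control point's collimator angle.
* `MLCFS ± m mm` changes the *total* field width by `m`: each bank moves
  by `m/2`. (Conventions differ in the error-sensitivity literature
  between per-bank and total-width; total-width keeps the nominal
  magnitude equal to the geometric size change.) Pairs that would close
  beyond the minimum gap are clamped to the gap centred at the pair
  midpoint.
* `MLCSHIFT ± m mm` moves both banks together by `m`.

Applied errors return modified deep copies; a `+m` shift followed by `−m`
restores the original plan exactly whenever no clamping occurred.

## The virtual detectors

**Diode array.** The helical diode arrangement is modelled as its
unwrapped-cylinder lattice: 21 axial rows × 66 circumferential columns at
10 mm pitch, odd rows offset +5 mm as the helix surrogate — 1386 diodes,
spanning 200 mm axially. A measurement bilinearly samples the rendered
dose at each diode, applies noise, and interpolates the scattered readings
onto the 5 mm export grid with a two-pass linear scheme (along each
staggered row, then across rows), nearest-value fill at the fringe. The
true helix geometry, entrance/exit summation and vendor angular
corrections are out of scope.

**Flat panel.** 1024 × 1024 pixels at 0.4 mm physical pitch. The
measurement samples the physical pixel lattice underlying a configurable
centred export crop (default 120 mm, which keeps desk-scale studies
tractable; the full 409.6 mm panel is available), applies noise per pixel,
and resamples bilinearly to the 0.255 mm export grid.

**Noise.** Multiplicative Gaussian, `value · (1 + ε)`,
`ε ~ N(0, σ_rel)`, independent per sampled element, with σ_rel = 0.001 by
default. This single knob stands in for the physical study's measurement
reproducibility and is calibrated by its observable: two independent
baseline measurements must pass 1%/1 mm global gamma at 100% on both
detectors, which the default satisfies with large margin (the worst-case
dose term of a noise-only comparison is ≈0.14 at 1%). There is no spatial
correlation and there are no dead pixels.

## The gamma engine

For every reference point at or above 10% of the reference maximum,

γ(r) = min over r′ of √( |r − r′|²/DTA² + (Dₑ(r′) − Dᵣ(r))²/(dd%·Dmax,ref)² ),

with the inclusive pass boundary γ ≤ 1. Two candidate models are
implemented:

* `interpolate = TRUE` (dense grids, the panel pathway): candidates are
  bilinear samples of the evaluated distribution on a 0.1 mm-step disc
  around each reference point.
* `interpolate = FALSE` (sparse grids, the array pathway): candidates are
  the evaluated grid nodes themselves.

Candidates are visited in order of increasing distance with early
termination once the distance term alone exceeds the current best γ. The
search window is **DTA-bounded**: its radius defaults to `2 × DTA`,
expanding once (doubled) only if it contains no candidate at all, and
points that still find no candidate fall back to the dose difference at
the nearest evaluated position. The window choice is deliberate and is
what reproduces the sparse-grid structural identity: on a 5 mm evaluated
grid no off-node lies within 4 mm, so at 2%/2 mm and 2%/1 mm every
assessed point reduces to its dose-only γ and GPR *and* GMV coincide
exactly — the behaviour observed for the cylindrical array in practice. A
window of 3×DTA would instead reach the 5 mm neighbours at 2%/2 mm and
break the GMV identity while leaving GPR untouched.

Two further numerical choices:

* The search step is a *fixed* 0.1 mm for every criteria setting rather
  than DTA/10. Nested candidate grids make per-point γ provably monotone
  under criteria loosening (a DTA-proportional step gives tighter criteria
  a finer grid and systematically lowers their γ for near-zero points,
  inverting GMV ordering).
* `gamma_brute_force()` — an independent, pure-R exhaustive minimisation
  over every evaluated node — is the oracle the compiled search kernel is
  tested against (agreement to 1e−12 with an unbounded window).

The comparison is directional (reference = baseline measurement,
evaluated = error variant); swapping the arguments changes the result and
a regression test pins the chosen direction.

## Resampling

`resample_dose()` changes a matrix's sampling resolution (bilinear by
default, nearest-neighbour retained to quantify kernel dependence),
preserving extent and cell-centre alignment, never extrapolating. In the
study pathway the 1 mm resolution setting resamples *both* matrices
before gamma analysis — an explicit pre-analysis step. The direction of
its effect differs by detector and is asserted qualitatively by the
acceptance suite: oversampling the 5 mm array grid to 1 mm *raises* mean
pass rates at 3%/3 mm and 2%/2 mm (interpolated nodes appear inside the
DTA window: optimistic bias), while undersampling the 0.255 mm panel grid
to 1 mm *lowers* the mean pass rate at 2%/1 mm (the bilinear
reconstruction is a contraction of the true field, so exact dose matches
become unreachable). Magnitudes are not asserted — they depend on the
synthetic plan cohort.

## Study design, seeding and detection

`run_study()` renders each patient's baseline once, measures it twice per
detector with independent noise seeds (reference and NE self-comparison),
then measures every error variant and compares it to the reference under
every criteria × resolution × detector × mode cell. Seeds derive
master → per-patient → per-measurement, all below 2³¹, so a study is
reproducible record-for-record from `master_seed` alone. An error is
*detected* when its GPR is strictly below the NE self-comparison GPR of
its cell (by calibration, 100). `composite_vs_individual()` repeats a
subset arc-by-arc and pairs the calls (an arc-based plan detects when
either arc does).

The default configuration applies the full 3 × 6 error grid to every
patient; `reference_roster(15, 88)` reproduces the clinical study's
bookkeeping instead (15 baselines + 88 variants → 206 comparisons, 824
analyses at four criteria), distributing variants by cycling because the
original DVH-based selection is not recoverable.

## Problem sizes used by the shipped tests

The test suite and acceptance checks run a deliberately scaled study: 3
patients, the full error grid, both detectors, four criteria, native and
1 mm resolutions, composite mode, 24 control points per arc, 0.5 mm
rendering over a 680 × 220 mm extent (covering the full diode lattice).
These sizes were chosen so the whole pipeline — about 450 gamma analyses
over 114 arc renderings — exercises every structural property at desk
scale. Properties asserted on cohort means (magnitude monotonicity,
resampling directions) use this cohort; nothing in the suite depends on
the physical study's measured pass-rate values, which are not reproducible
without its (undeposited) measurement data.

## What the synthetic cohort does and does not show

The generator emulates geometry and sampling, not clinical dose: targets
are smooth quasi-elliptical apertures with bounded (≤3 mm) leaf
modulation, so rendered fields are more rotationally symmetric and less
modulated than clinical lung SBRT deliveries. Consequences worth knowing:

* Collimator errors are intrinsically harder to see here than in clinical
  plans — a near-circular aperture rotated by 5° barely changes. The
  synthetic study therefore reproduces the finding that *small* collimator
  errors (±1°, ±2°) go undetected, but unlike the physical study it may
  not detect ±5° either. MLC field-size and shift errors behave as in the
  physical study (detected, monotone in magnitude, DD-dominated on the
  array, DTA-sensitive on the panel).
* Absolute pass rates are not comparable to clinical tables: the virtual
  array assesses fewer above-threshold points than a physical
  entrance+exit measurement, and the synthetic fields are simpler. All
  package-level claims are therefore structural (identities, orderings,
  directions), plus the NE measurement-to-measurement standard of 100%.
* Noise is uncorrelated and multiplicative only; detector-specific
  response (field-size dependence, angular corrections, image lag) is out
  of scope.

## A worked example

```{r example, eval = FALSE}
library(doseqa)

plan <- generate_patient_plan(seed = 1, target_diameter = 35)
dose <- render_composite_dose(plan, extent = c(680, 220))

array <- build_arccheck_lattice()
baseline <- measure(dose, array, noise_model(0.001, seed = 11))

shifted <- apply_error(plan, error_spec("MLCSHIFT", 2))
variant <- measure(render_composite_dose(shifted, extent = c(680, 220)),
                   array, noise_model(0.001, seed = 12))

gamma_index(baseline, variant, gamma_criteria(2, 2),
            search_options(interpolate = FALSE))

st <- run_study(study_config(n_patients = 3, resolutions = c("native", "1mm")))
aggregate_study(st)
```
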