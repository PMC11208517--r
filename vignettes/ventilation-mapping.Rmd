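---
title: "Micro-CT lung densitometry and ventilation mapping: models, parameters, design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micro-CT lung densitometry and ventilation mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models it
implements, the assumptions they rest on, the tunable parameters and their
defaults, what the synthetic phantom does and does not emulate, and the
design decisions taken where the method left choices open.

## 1. The measurement model

### 1.1 Densitometry

CT attenuation in the lung is, to a good approximation, a linear mixture of
air (−1000 HU) and soft tissue (≈ 0 HU). Two consequences drive everything
in this package:

* **Aeration compartments.** A voxel's HU value places it on the
  air–tissue axis, so fixed HU ranges partition the lung into
  normo-aerated `[−860, −435]`, hypo-aerated `(−435, −121)` and
  non-aerated `[−121, 121]` compartments (preclinical ranges; brackets are
  part of the contract — a voxel at exactly −435 HU is normo-aerated, at
  exactly −121 HU non-aerated). We additionally report `%Other` for voxels
  outside all three ranges (chiefly hyper-aerated voxels below −860 HU)
  rather than dropping them: the denominator of every percentage is all
  region voxels, so the four percentages sum to 100 exactly. Whether
  hyper-aerated voxels belong in the denominator is genuinely
  under-determined in the field; our choice is declared and the boundaries
  are configurable in `analysis_config()`.

* **Gas–tissue decomposition.** The same mixture model gives a per-voxel
  gas fraction `g = clamp(−HU/1000, 0, 1)`; summing `g` and `1 − g` times
  the voxel volume yields gas and tissue volumes and `%Gas`. This is the
  standard CT densitometry convention and the one consistent with the
  specific-volume formula below; the exact formulas behind the published
  supplementary readouts were not available, so this convention is our
  declared implementation.

### 1.2 Specific gas volume and ventilation

The specific volume of lung tissue-plus-gas follows from HU directly,
`SV_lung (ml/g) = 1000/(HU + 1000)`, and subtracting the specific volume of
lean tissue (`1/1.065 = 0.939 ml/g`, a fixed literature constant exposed as
`tissue_specific_volume_ml_per_g`) gives the specific gas volume

```
SVg = 1000/(HU + 1000) − 0.939  [ml/g]
```

SVg is strictly decreasing in HU and crosses zero near 65 HU: a
tissue-density voxel carries no gas. The formula diverges at −1000 HU, so
HU is clipped to `[−990, 1000]` before the division (bounding SVg at about
99 ml/g); the clip range is configurable. Ventilation is the change in air
content per gram of tissue between phases, `ΔSVg = SVg_P01 − SVg_P02`,
computed voxel-by-voxel *after* spatially matching the expiratory to the
inspiratory volume. ΔSVg is only defined where both phases have lung, so
all maps and classification denominators are restricted to the
intersection of the P01 mask and the warped-P02 mask.

### 1.3 Registration

Expiratory-to-inspiratory matching uses the classic Demons algorithm,
multi-resolution, on Laplacian-of-Gaussian-filtered images. The LoG
prefilter (σ = 1 voxel by default) removes the DC component — lung
intensity changes with inflation, and registering raw HU would chase that
global change instead of structure. Filtered images drive the registration
only; **densitometry and SVg always use warped raw-HU images**.

Declared conventions and defaults (the originating method publishes none,
so these are pinned in `registration_params()` and fully config-exposed):

* Field convention: defined on the fixed (P01) grid, pull-back
  (`warped(x) = moving(x + u(x))`), vectors in mm.
* 3 levels (4×/2×/1× downsampling), 100/50/25 iterations, Gaussian
  smoothing of the accumulated field with σ = 1.5 voxels per iteration,
  convergence on relative MSE change < 1e−4.
* Per level the loop tracks the best-so-far field and stops after 10
  iterations without MSE improvement, reverting to the best field.
  Without this, over-iterating at the coarsest level drifts on
  reconstruction noise (observed as a slow MSE creep after the minimum).
  A divergence error fires only when the update magnitude grows for 10
  consecutive iterations *and* the MSE is substantially (>1.5×) above its
  best — a genuinely runaway registration, not the benign early build-up.
* Registration runs on full volumes; evaluation (endpoint error, volume
  consistency) is lung-restricted. Whether the original workflow masked
  registration to the thorax is unstated; full-volume is the simpler
  declared default.
* Interpolation: trilinear for HU (out-of-field = −1000), nearest for
  labels (out-of-field = background), so warped label volumes keep the
  label set.

### 1.4 Threshold calibration and the three-class classifier

On a basal (day-0, pre-challenge) cohort, per animal we take the 5th
percentile of inspiratory SVg, the 5th percentile of (warped) expiratory
SVg and the 25th percentile of ΔSVg over the classification domain;
`α_I`, `α_E`, `β` are the means of these per-animal percentiles. The
phrase "basal mean distribution" admits a second reading — percentiles of
the pooled voxel distribution — and both are implemented
(`calibration_pooled`); neither is asserted to be the original study's
exact choice. Per-animal-then-mean is the default because it weights
animals equally regardless of lung size.

Classification assigns every domain voxel exactly one class:

1. `ΔSVg ≥ β` → **Normal** (the boundary voxel is Normal: the condition
   is `≥`);
2. otherwise, `SVg_P01 < α_I` **and** `SVg_P02 < α_E` → **Fibrosis**
   (dense, non-ventilating in both phases);
3. otherwise → **Low** (reduced ventilation not due to fibrosis).

The mixed cases — reduced ventilation with exactly one per-phase SVg
condition met — are not defined by the three-class table; we route them to
Low, because Fibrosis is the conjunction of all three conditions and
anything failing it but ventilation-reduced is by elimination "reduced
ventilation, not due to fibrosis". `mixed_class = "separate"` reports them
as a fourth class instead. By construction of the percentiles,
re-classifying the calibration cohort itself yields ≈75% Normal vent and
≈5% of voxels below `α_I` — a self-consistency property the acceptance
suite asserts.

## 2. The synthetic thorax phantom

### 2.1 What it emulates

The phantom stands in for reconstructed free-breathing micro-CT pairs of a
mouse thorax: a soft-tissue body ellipsoid (40 HU) containing two disjoint
lung ellipsoids whose voxels draw from N(−550, 45²) HU, surrounded by
−1000 HU air, on a 50 µm isotropic grid; additive Gaussian reconstruction
noise (default SD 25 HU) on both phases; focal fibrotic lesions as
near-tissue-density spheres (N(20, 40²) HU) with an apical, left-dominant
placement bias mirroring the lesion topography of bleomycin fibrosis
models; and a smooth respiratory deformation coupling density change to
local volume change.

### 2.2 The mass-conserving deformation

The inspiration→expiration motion is analytic and purely axial:

```
u_z(x, y, z) = −A · w(x, y) · S(z) · (1 − s·L(x, y, z))
```

with `A` the peak apex displacement (default 0.15 mm = 3 voxels), `w` a
Gaussian in-plane window (σ = `smoothness_mm`), `S` a smoothstep rising
from the lung base to the apex, and `L` a smoothed lesion indicator with
stiffness `s` (default 0.9): fibrotic tissue deforms near-rigidly, so its
ΔSVg stays near zero — which is precisely what the classifier's third
condition needs to be testable. The indicator is dilated before smoothing
so the stiffening covers the entire lesion including its rim; smoothing
the raw indicator would leave a compliant shell just inside the lesion
boundary whose voxels compress and ventilate, contradicting the
near-rigid-lesion premise.

Because the field is axial and monotone per (x, y) column, it is inverted
exactly per column, and the expiratory image is built by the
mass-conserving intensity rule

```
HU_exp = (HU_insp + 1000)/J − 1000,  J = local Jacobian determinant,
```

so pure gas (−1000 HU) is invariant under any compression and total tissue
mass `Σ (HU + 1000)/1000 · v_voxel` agrees between phases to within 1% at
the default amplitude (a property test). An analytic-plus-numeric Jacobian,
the true displacement field and the true expiratory mask are returned as
ground truth, which is the reason the deformation is analytic rather than
biomechanical: oracles need exactness, not realism.

### 2.3 What a green test does not establish

The phantom contains no airway tree, no lobar fissures, no cardiac or
gating artifacts, no beam hardening, and its deformation is axial rather
than a full diaphragm/rib-cage kinematic. Green registration and
classification tests therefore establish correctness of the algorithms
under the stated model, not performance on real scans; in particular the
classical segmenter's near-perfect Dice on phantoms says nothing about
real-thorax segmentation, which the original workflow delegated to a
learned model (out of scope here; external masks are accepted via
`load_external_mask()`).

### 2.4 The longitudinal cohort generator

`cohort_plan()` encodes the study design: groups SAL / BLM / NINT_7_28 /
NINT_14_28, scan days 0–28, day 0 lesion-free for everyone (it is the
calibration set), treatment start days on the scan grid. No quantitative
between-day lesion-growth curve is published, so the growth rule is a
declared modeling choice: each subject keeps fixed lesion centers whose
radii grow as `severity^(1/3)` (volume tracks severity), severity grows
linearly with day for untreated fibrotic groups and at
`treated_growth_factor` (default 0.25) of that rate after a group's
treatment start. This makes per-subject lesion burden non-decreasing
(nested spheres) and treated burden strictly below untreated at the final
day — the qualitative pattern the end-to-end direction test asserts;
no effect size is claimed.

## 3. Numerical choices and degenerate inputs

* HU stored as doubles regardless of source integer type; NIfTI written as
  float32 (volumes/fields) and int16 (labels).
* Grid compatibility = equal shapes and spacings within 1e−6 mm; all
  readers and stages reject mismatches rather than resampling silently.
* Quantiles use R's default (type 7) definition.
* Empty regions are errors in the morphometrics; empty segmentations are
  errors, surfaced as QC flags (`segmentation-failure`,
  `registration-failure`, `thresholds-absent`) by the pipeline rather than
  dropping subjects; fold-change rows with a zero baseline are `NA`, and
  fibrosis percentages are reported raw because their baseline is ≈0.
* Tidal volume may be negative and is reported as such — a negative TV is
  a segmentation/registration fault indicator, not a value to clamp.
* The left/right split labels two substantial components by centroid
  laterality (lower x = left = 1); fused lungs fall back to the sagittal
  plane through the mask centroid. Whether the original split includes
  mediastinal structures at the hilum is unstated; the fallback is our
  declaration.
* Determinism: all stochastic stages consume explicit seeds; fixed inputs
  give bit-identical volumes, fields and CSVs (asserted by tests).

## 4. Known limitations

* The classical segmenter under-segments lesions touching the lung
  boundary (hole filling only recovers enclosed dense regions); workflows
  with trusted masks should supply them.
* Classic (non-diffeomorphic) Demons does not guarantee an invertible
  field; the phantom deformations it is validated on are well within the
  regime where it behaves diffeomorphically.
* Calibration semantics ("per-animal mean" vs "pooled") and the Normo
  denominator are implemented as switches, but no claim is made about
  which variant matches the original study exactly.
* Inferential statistics (ANOVA, post-hoc tests) are deliberately out of
  scope; the cohort tables are tidy inputs for any statistics environment.
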