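---
title: "Quantifying choroidal thickness and vascularity from OCT volumes"
author: "choroquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying choroidal thickness and vascularity from OCT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its methods: the measurement
model, the numerical choices behind each stage, what the synthetic phantom
does and does not emulate, and the limitations a user should know about.

## Measurement model

A structural OCT volume is a nonnegative intensity array indexed
`[y, x, z]` — B-scan row, A-scan column, axial sample — with `z = 1` on the
vitreous side.  Physical position is `(index − 1) × spacing`; the default
geometry is a 12 × 12-mm field (24 µm between A-scans at the native
500 × 500 sampling) with 1.95-µm axial sampling.  The choroid of one A-scan
is the half-open voxel interval `[BM, CSI)` between Bruch's membrane and the
choroidal–scleral interface.  Two scalars summarize it:

* **thickness** `(CSI − BM) × Δz` in µm, and
* **CVI**, the fraction of choroidal voxels that lie inside vessel lumens.

Both are computed per A-scan, giving en face maps, and then averaged
(unweighted over included A-scans) inside fovea-centered regions.

## Attenuation compensation

OCT signal decays with cumulative tissue extinction, so structures beneath
strong absorbers (RPE, pigment epithelial detachments, media opacities) sit
in shadow.  The depth-resolved compensation used here divides each voxel's
(exponentiated) intensity by the remaining tail energy of its A-scan:

$$A_c(z) = \frac{I(z)^n}{2\sum_{z' \ge z} I(z')^n + \epsilon}.$$

If backscattered intensity is proportional to the local extinction
coefficient and essentially all energy is attenuated within the imaged
depth, this cancels the accumulated extinction exactly and the corrected
signal is proportional to the local extinction — depth-flat within a
homogeneous tissue and invariant to any multiplicative shadow cast from
above.  The exponent `n` (default 2) is exposed as a parameter because the
compensation family differs in this choice; `ε` defaults to
`1e-8 × max(I)^n`, making the output invariant to global rescaling of the
input.  Near the bottom of the volume the tail becomes short and the
quotient unreliable, which is why segmentation bands keep a guard margin
above the last samples.

## Surface segmentation

Each B-scan is segmented independently by a minimum-cost path over its
columns (dynamic programming), with the cost at `(x, z)` the signed axial
derivative of a Gaussian-smoothed volume and transitions limited to
`max_step` voxels per column (default 2); ties break toward the smaller
depth, and the exported `dp_min_path()` is verified against exhaustive path
enumeration in the tests.  A parabolic fit around the integer optimum gives
sub-voxel precision, and a 3 × 3 median filter across the en face grid
suppresses isolated column failures.

*Bruch's membrane* is searched on the **raw** volume in a band around the
per-A-scan intensity argmax: the RPE complex is the dominant reflector in
raw structural OCT, a property the compensated volume deliberately destroys
(compensation equalizes tissues by extinction).  The BM is the strongest
bright-to-dark edge at the RPE base.

*The CSI* is searched on the **compensated** volume strictly below the BM
(default at least 30 µm below, keeping clear of the RPE-base edge — pass
`min_thickness_um = 0` for a known near-zero choroid).  After compensation
the choroid is depth-flat while the inner sclera is markedly dimmer, so at
the CSI-search smoothing scale (σ ≈ 3 voxels axially, 2 A-scans laterally)
the coherent CSI step outweighs scattered vessel-wall edges; an optional
grey-scale closing along depth can additionally fill vessel lumens, but is
off by default because wide closings can also fill the hyporeflective inner
sclera.  The dynamic program localizes an edge at its midpoint, half a
voxel above the first voxel of the deeper tissue; `segment_choroid()` adds
0.5 so surfaces are boundary voxel indices consistent with the half-open
slab convention.  CSI columns falling above the BM are clamped to it; more
than 5% clamped columns is reported as a segmentation failure rather than
silently repaired.

Manual corrections — the replacement for an interactive grading step — are
sparse `(surface, y, x, z)` records applied by `apply_corrections()`, which
re-validates the `BM ≤ CSI` invariant and tracks per-A-scan provenance.

## Vessel binarization and CVI

Vessels are segmented from the *entire choroidal slab of one eye-visit* with
a single global Otsu threshold.  `otsu_threshold()` scans the 256-bin
histogram's bin edges and maximizes the between-class variance
`n₀n₁(m₀ − m₁)²` with class means computed exactly from per-bin sums; ties
break toward the lower threshold, and the tests compare it against an
exhaustive edge scan.  A slab voxel is a vessel voxel iff its value falls
*below* the threshold — lumens are hyporeflective in structural OCT.

Two numerical choices matter in front of the threshold
(`despeckle_volume()`):

* the corrected intensities are mapped to a **logarithmic scale** first.
  OCT speckle is multiplicative, so on the log scale the vessel and stroma
  classes have equal spread and the between-class-variance split is
  unbiased; on the linear scale the wider bright class drags the threshold
  upward and inflates CVI.
* despeckling is **axial only** (running median of 7 samples plus a σ = 2
  Gaussian): at wide-field A-scan spacing choroidal vessels are laterally
  thin, and lateral averaging would destroy their contrast.

After thresholding, `clean_vessel_mask()` applies an axial majority vote
(window 9) inside the slab, removing isolated misclassified voxels while
preserving vessel cross-sections wider than half the window.

The CVI map divides per-A-scan vessel counts by slab counts over
`[round(BM), round(CSI))`; surfaces are rounded half-up so the counting is
pure integer arithmetic, and the global ratio equals the slab-count-weighted
mean of the map exactly.  The *regional* CVI reported downstream is the
unweighted mean of the per-A-scan map (the map's definition); the pooled
voxel ratio is available via `cvi_global()` for users who prefer the
volume-weighted summary.

## Registration and longitudinal comparability

Visits of one eye are aligned rigidly — translation plus rotation about the
image center, no scale (axial-length magnification differences are a known,
deliberate omission) — to the day-of-exudation visit, which every eye has.
Candidate rotations on a ±5° grid in 0.25° steps are each resolved to a
translation by phase correlation with local DFT upsampling (0.1-px
resolution), and the candidate with the best normalized cross-correlation
after warping wins.  Scalar maps are warped with bilinear interpolation
(missing outside), masks with nearest-neighbour (`FALSE` outside, so a warp
can never invent exclusion pixels).

## Regions, exclusions, eligibility

The "5-mm" and "11-mm" circles are *diameters* (an 11-mm radius cannot fit
a 12-mm scan, and the rim's 6-mm quoted width matches the diameter
difference); the rim is the set difference of the two circles, making the
area-weighted identity `n₅m₅ + n_rim m_rim = n₁₁m₁₁` exact.  Pixel
membership is a pixel-center test in physical units.  The analysis mask of
a region removes the optic nerve head and the union of all visits' manual
exclusion masks in the reference frame — an area unreliable at any visit is
excluded from every visit, so longitudinal changes are computed over
identical areas.  An eye leaves the CVI analysis when the excluded area
exceeds 10% of its 5-mm circle; exactly 10% is still eligible (the rule is
a strict "more than").

## Statistics

Longitudinal comparisons are change-score analyses: per-eye differences
between two visits, matching the increase/decrease/change rows of a
three-visit report, with eyes missing a visit dropped and logged.
Significance comes from linear regression with cluster-robust variance,
clusters being patients (fellow eyes share a cluster):

$$V = c\,(X'X)^{-1}\Big[\sum_g X_g'e_g e_g'X_g\Big](X'X)^{-1},$$

with `c = G/(G−1)·(N−1)/(N−k)` (CR1, the default; CR0 sets `c = 1`) and a
t reference distribution on `G − 1` degrees of freedom — the standard
small-sample practice when the source analysis names only "cluster-robust
variance estimation".  The paired mean test is the intercept-only fit on
changes; the MNV-type comparison adds an indicator of type 3 (types 1 and 2
are grouped, both arising from the choroidal circulation) and reads the
indicator coefficient.  Under singleton clusters CR0 reduces to the HC0
heteroskedasticity-robust estimator exactly, one of the tested identities;
the estimator is also cross-checked against an independent implementation
(`sandwich::vcovCL`).  No multiplicity adjustment is applied, matching the
source analysis.

## The synthetic phantom

The phantom provides ground truth that patient data cannot: per-A-scan
surfaces, thickness, vessel voxels and programmed longitudinal effects.
Per A-scan it stacks vitreous, retina, a thin bright RPE band ending at the
BM, a choroid of bright stroma (level 180) with dark vessel cylinders
(level 60) down to the CSI, and sclera.  Design choices:

* **Band-limited anatomy.** BM depth and thickness are bilinear
  interpolations of coarse seeded noise, returned as closures over
  continuous coordinates so longitudinal visits can evaluate the same
  anatomy under a rigid transform without resampling error.
* **Vessels** are cylinders with axes in the en face plane at a fixed
  fraction of the local slab depth, radii 20–60 µm, placed with an
  anti-overlap bias until the global vessel fraction is within ±0.01 of the
  target (default 0.6, the vascularity scale of this disease range).
  Centers are sampled from a margin-extended window so the vessel density
  is statistically homogeneous out to the grid edges — without this the
  fovea-centered regions would see a higher density than the field average.
* **Model-consistent optics.** Per-tissue extinction defaults to
  `(level/180)² × 2.5e-3 µm⁻¹`, i.e. backscattered intensity proportional
  to extinction — precisely the regime the exponent-2 compensation assumes,
  under which the corrected choroid is depth-flat.  The scleral
  reflectivity grades from 40 at the CSI to 400 over 120 µm (the inner
  sclera is hyporeflective next to the stroma, then backscatter rises with
  depth); besides realism this guarantees the imaged depth captures
  essentially the whole backscatter tail, without which the compensation
  quotient diverges above the volume bottom.
* **Speckle** is multiplicative gamma noise with shape 4 (sd = 0.5 of the
  mean), a standard approximation of fully developed OCT speckle; truth is
  recorded before noise.  Shadow artifacts are explicit discs multiplying
  the signal below a given depth by a constant factor, emulating media
  opacities and PED shadowing.
* **Scale.** The default grid is 64 × 64 × 256 voxels covering the full
  12 × 12-mm field (so lateral spacing grows to 187.5 µm while all regional
  geometry still fits); `full_scale = TRUE` switches to the native
  500 × 500 × 1536.  The reduced grid keeps a full three-visit pipeline run
  under ten seconds and the complete validation suite in minutes; every
  geometric quantity is parameterized in physical units, so conclusions do
  not depend on the grid.
* **Cohorts.** Measurements are `baseline + patient effect + eye effect +
  visit delta + residual`, all Gaussian; a patient contributes a fellow eye
  with probability 4/37, sharing the patient effect.  Defaults program a
  200.7-µm baseline, +12.7 µm at exudation and −19.5 µm after treatment
  (CVI 0.617, +0.014, −0.017), with the residual SD set to the observed
  change SD divided by √2 and the patient/eye SDs partitioning the
  remaining cross-sectional variance.

What the phantom does **not** emulate: MNV lesion morphology, retinal
vessels and their OCTA flow signal (registration features are taken from
choroidal-slab projections instead), partial-volume rendering at tissue
boundaries, axial-length scaling differences between eyes, and any
interferometric effects (roll-off, defocus, motion artifacts).  Passing
tests therefore demonstrate the correctness and stability of the
measurement chain under controlled optics — not clinical accuracy on
pathological scans, which still requires manual review of segmentations and
exclusion outlines.

## Known limitations

* The CSI polarity assumption (stroma brighter than inner sclera after
  compensation) can fail in eyes with an atypical sclera; the
  `segment_surface()` primitive accepts arbitrary bands and polarities for
  such cases, and manual corrections override the automatic result.
* A global Otsu threshold adapts to each visit's histogram; when the true
  vessel fraction changes between visits, the threshold moves with it and
  small CVI *changes* are attenuated relative to truth.  Level recovery is
  accurate to ±0.02; programmed changes of ±0.015 are recovered in
  magnitude only to that same ±0.02 envelope.
* Rotation recovery is quantized to the 0.25° search step.
* Cluster-robust inference relies on the number of clusters (37 at the
  study conditions); Monte-Carlo coverage of the CR1/t(G−1) interval is
  94–95% over 2000 simulated cohorts, inside the expected [0.92, 0.98]
  band, but very small cohorts would need wild-bootstrap refinements that
  are out of scope here.
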