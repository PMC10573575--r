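# choroquant

Volumetric quantification of the choroid from swept-source OCT, with
cluster-robust longitudinal statistics.

## The problem

In exudative age-related macular degeneration (eAMD), macular
neovascularization (MNV) leaks fluid and is treated with intravitreal
anti-VEGF injections.  The choroid — the vascular bed between Bruch's
membrane (BM) and the choroidal–scleral interface (CSI) — thickens as
exudation develops and thins again under treatment.  Quantifying that course
over a whole 12 × 12-mm scan, rather than a single subfoveal B-scan,
requires a chain of image-analysis steps that this package implements as
tested, reusable components:

1. **Attenuation compensation** — per A-scan, the depth-resolved correction
   `A_c(z) = I(z)^n / (2 Σ_{z'≥z} I(z')^n + ε)` (default `n = 2`), which
   removes shadowing from overlying tissue and sharpens the CSI.
2. **Surface segmentation** — BM and CSI by per-B-scan minimum-cost paths
   (dynamic programming on the signed axial derivative of a smoothed
   volume, step-constrained across A-scans), with optional sparse manual
   corrections applied from CSV.
3. **En face maps** — choroidal thickness `(CSI − BM) × Δz` and the
   choroidal vascularity index (CVI): choroidal vessels are binarized from
   the whole choroidal slab by global Otsu thresholding, and CVI at each
   A-scan is the ratio of vessel voxels to slab voxels.
4. **Registration** — follow-up visits are rigidly aligned to the
   day-of-exudation visit by phase correlation with subpixel refinement over
   a rotation search, so all visits are measured over the same retinal area.
5. **Regions and exclusions** — fovea-centered 5-mm and 11-mm circles and
   the 6-mm-wide rim between their boundaries; the optic nerve head and
   manually outlined artifact areas (union over all visits) are excluded,
   and an eye is dropped from CVI analysis when more than 10% of its 5-mm
   circle is excluded.
6. **Statistics** — per-eye change scores between visits, summarized as
   mean ± SD, tested with linear regression using cluster-robust (sandwich)
   variance `V = c (X'X)⁻¹ [Σ_g X_g'e_g e_g'X_g] (X'X)⁻¹` (CR1 by default,
   t on G − 1 df) because fellow eyes of one patient are correlated.

Because clinical OCT volumes cannot be redistributed, the package ships a
**synthetic phantom generator**: 3-D scans with a smoothly varying choroid,
hyporeflective vessel cylinders placed to a prescribed vascularity, forward
per-tissue attenuation, shadow artifacts and gamma speckle — with exact
ground truth (surfaces, thickness map, vessel mask, per-A-scan vessel
fraction, applied inter-visit transforms) recorded before noise.  A cohort
simulator produces longitudinal measurement tables with fellow-eye
clustering and programmed visit effects.

## Worked example

Simulate a three-visit eye with the programmed course (+12.7 µm thickness
and +0.014 CVI from pretreatment to the day of exudation, then −19.5 µm and
−0.017 after treatment), quantify it end to end, and inspect the 5-mm-circle
records:

```r
library(choroquant)
series <- generate_longitudinal_phantoms(phantom_params(seed = 7))
q <- run_quantify(lapply(series, `[[`, "volume"), pipeline_config())
subset(q$records, region == "circle5")[, c("visit", "metric", "value", "n_pixels")]
#>           visit       metric    value n_pixels
#>    pretreatment thickness_um 152.2315      556
#>    pretreatment          cvi   0.5812      556
#>       exudation thickness_um 164.9859      556
#>       exudation          cvi   0.5862      556
#>  post_treatment thickness_um 144.9533      556
#>  post_treatment          cvi   0.5779      556
```

The recovered thickness course is +12.75 µm then −20.03 µm against the
programmed +12.7/−19.5, and the CVI values track the phantom's true vessel
fractions (0.588, 0.602, 0.589) to within 0.02.  Each value is the
unweighted mean over the 556 A-scans of the 5-mm circle that survive the
exclusion masks.

Cohort-level analysis on a simulated population (37 patients, 41 eyes,
fellow-eye clustering) reproduces the three-comparison report:

```r
cohort <- generate_cohort(cohort_params(seed = 1))
tabs <- run_analyze(cohort_to_records(cohort), pipeline_config())
writeLines(format_tables(tabs))
#> == pre_to_exudation ==
#> thickness_um   circle5   n=41  increase:  18.483 +/- 22.359   (visit means 191.601 -> 210.084)   P=6.6e-06
#> cvi            circle5   n=41  increase:   0.014 +/-  0.022   (visit means 0.618 -> 0.633)   P=0.00022
#> == exudation_to_post ==
#> thickness_um   circle5   n=41  decrease:  19.771 +/- 22.890   (visit means 210.084 -> 190.313)   P=1.2e-06
#> cvi            circle5   n=41  decrease:   0.014 +/-  0.022   (visit means 0.633 -> 0.619)   P=0.00034
#> == pre_to_post ==
#> thickness_um   circle5   n=41  change:  -1.288 +/- 24.812   (visit means 191.601 -> 190.313)   P=0.72
#> cvi            circle5   n=41  change:   0.001 +/-  0.019   (visit means 0.618 -> 0.619)   P=0.85
```

The pattern mirrors the clinical course: a significant rise to the day of
exudation, a significant fall after treatment, and no significant
pretreatment-to-post-treatment difference.  "decrease" rows are reported
positive when the measurement fell.

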