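# gtvconc

Geometric concordance analysis of radiotherapy gross target volumes (GTVs)
for thoracic esophageal cancer.

When a patient planned for radiotherapy already has a diagnostic FDG-PET/CT,
the planning target can be contoured three ways: on the planning CT alone
(GTV_3D), on the planning CT while visually referencing the PET/CT
(GTV_PET-ref), or by SUV-threshold auto-contouring on the PET/CT deformably
registered to the planning frame (GTV_PET-reg). How well these three
contours agree — in position, volume, shape and overlap — determines whether
a diagnostic PET/CT is good enough to drive target definition. `gtvconc`
implements that concordance analysis end to end for simulated (or
user-supplied) image data:

- **phantom**: digital thorax phantoms — paired planning-CT (HU) and PET
  (SUV) volumes containing a cylindrical esophageal tumor at an upper,
  middle or distal location, plus ground-truth masks and three contour
  variants with *known* perturbations (COM shift, length/radius change,
  residual deformation), at single-patient or 72-patient cohort scale
  (32/24/16 per location group).
- **delineate**: the two clinical contouring rules. CT: mediastinal window
  (width 400 HU, level 40 HU), keeping slices whose esophageal wall
  thickness exceeds 5 mm or whose non-gas wall diameter exceeds 10 mm.
  PET: threshold at `max(2.5, 0.20 * SUVmax)` inside an ROI sphere, with an
  SUVmax >= 2 enrollment check and heart repair (organ subtraction).
- **metrics**: for masks A, B on one grid —
  center-of-mass displacement per axis and the 3D vector
  `V = sqrt(dx² + dy² + dz²)`; conformity index `CI = |A∩B| / |A∪B|`
  (Jaccard; 1 iff identical); degree of inclusion `DI(A in B) = |A∩B| / |A|`
  (so `1 − DI(A in B)` of A is unnecessarily irradiated if B is truth);
  Dice score; symmetric Hausdorff distance; volume (cm³), cranio-caudal
  length (cm) and maximum transverse diameter (cm).
- **cohort_stats**: per-group summaries (median, IQR, mean ± SD), Wilcoxon
  signed-rank (exact for small n, tie-corrected normal approximation
  otherwise), paired t, and Spearman correlation, assembled into five
  report tables stratified by tumor location.
- **io / pipeline**: NIfTI volume/mask I/O with mm spacing, YAML
  configuration, and a deterministic `run_all()` orchestrator
  (simulate → delineate → compare → stats) plus a CLI
  (`inst/cli/gtvpipe.R`).

## Worked example

```r
library(gtvconc)

spec <- phantom_spec(tumor_location = "middle", tumor_suvmax = 12.95, seed = 42)
patient <- make_phantom(spec)
patient
#> <synthetic_patient> B-00000042 (group B), tumor middle, 7168 truth voxels

roi <- threshold_spec(roi_center = patient$meta$tumor_center, roi_radius = 40)
gtv_pet <- suv_threshold(patient$pet_suv, roi)
sprintf("SUVmax %.2f -> effective threshold %.2f SUV",
        attr(gtv_pet, "suvmax"), attr(gtv_pet, "threshold"))
#> "SUVmax 13.78 -> effective threshold 2.76 SUV"

gtv_pet <- exclude_heart(gtv_pet, patient$heart_mask)
ov <- overlap(gtv_pet, patient$truth_mask)
sprintf("CI %.3f, DI(auto in truth) %.3f, Dice %.3f, Hausdorff %.1f mm",
        ov$ci, ov$di_a_in_b, ov$dice, ov$hausdorff)
#> "CI 0.965, DI(auto in truth) 0.965, Dice 0.982, Hausdorff 1.0 mm"

d <- displacement(gtv_pet, patient$truth_mask)
sprintf("V = %.2f mm", d$vector_v)
#> "V = 0.01 mm"

sh <- shape_measures(gtv_pet)
sprintf("volume %.1f cm^3, length %.1f cm, max transverse diameter %.1f cm",
        sh$volume, sh$length, sh$max_transverse_diameter)
#> "volume 22.3 cm^3, length 4.8 cm, max transverse diameter 2.5 cm"
```

The SUVmax reported (13.78) exceeds the nominal 12.95 because it is read
from the noisy PET inside the ROI, exactly as an operator would; the
threshold follows as `0.20 * 13.78 = 2.76 > 2.5`. The auto-contour agrees
with the ground-truth tumor to CI 0.97 with a 1 mm Hausdorff distance —
the residual disagreement lives in the uptake taper zone at the tumor
surface.

A full cohort study runs as

```r
res <- run_all(pipeline_config(seed = 1), out_dir = "out")
res
#> <cohort_result> n = Total=72, A=32, B=24, C=16
#>   CI GTV_PET-reg and GTV_PET-ref  M 0.66 (IQR 0.55, 0.73)  0.63 +- 0.14
#>   CI GTV_PET-reg and GTV_3D       M 0.73 (IQR 0.66, 0.83)  0.72 +- 0.13
#>   CI GTV_PET-ref and GTV_3D       M 0.76 (IQR 0.66, 0.83)  0.73 +- 0.12
```

writing per-patient masks, the cohort manifest, per-patient metrics, and
the five report tables (3D-vector displacements, volumes,
lengths/diameters, CI, DI) with their Wilcoxon / paired-t / Spearman
results under `out/`.

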