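---
title: "Methods: simulating and measuring GTV concordance"
author: "gtvconc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring GTV concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In esophageal-cancer radiotherapy, the gross target volume (GTV) of the
primary tumor can be contoured from different image sources: the planning
CT alone (GTV_3D), the planning CT with visual reference to a diagnostic
FDG-PET/CT (GTV_PET-ref), or a deformably registered PET/CT with
SUV-threshold auto-contouring (GTV_PET-reg). Whether the three agree — and
how agreement depends on tumor location in the thorax — is a geometric
question about triples of 3D binary masks. `gtvconc` provides a controlled
setting for that question: a phantom generator with known ground truth,
rule-based delineation operators, the standard concordance metrics, and the
paired cohort statistics, wired into one reproducible pipeline.

Clinical image data for this design are not publicly deposited, so the
package treats synthetic data generation as a first-class, tested module
rather than a fixture.

## The phantom

A patient phantom is a pair of co-registered volumes on one grid (default
128 x 128 x 160 voxels at 1 x 1 x 3 mm; dimension order LR, AP, CC; a 3 mm
slice thickness is typical of planning CT — the geometry is configurable
because clinical acquisition parameters vary):

* **Planning CT (HU).** Lung background (-750 HU) with a soft-tissue
  mediastinal block (40 HU), an esophageal tube along CC (lumen gas
  -1000 HU, wall 45 HU; lumen radius 2 mm, normal wall 2.5 mm, so the
  uninvolved esophagus stays below both contouring rules), and for
  middle/distal tumors a heart sphere (radius 24 mm). A -300 HU shell
  (2.5 mm) separates the esophagus from the mediastinal block the way a
  periesophageal fat plane would; its value is chosen far enough below the
  mediastinal window floor (-160 HU) that CT noise cannot bridge the gap.
  The tumor is a wall-thickened cylindrical segment; at the default
  `wall_thickness = tumor_radius` it occludes the lumen (solid), while
  smaller wall thicknesses give an annular thickening with a patent lumen.
* **PET (SUV).** Background SUV 1.0, heart SUV 1.8 (below the 2.5
  delineation floor, as myocardial uptake usually is; raise `heart_suv` to
  exercise heart repair). Tumor uptake plateaus at `tumor_suvmax` in the
  core and falls to background along a cosine taper of the signed distance
  to the tumor surface.

The taper shell is asymmetric: 4 mm inside the surface to 1.5 mm outside.
This is a deliberate numerical choice. The effective auto-contour threshold
is `max(2.5, 0.20 * SUVmax)`; expressed as a fraction of the
background-to-peak range, that threshold sits between about 0.13 and 0.68
over the admissible SUVmax range 3.21-49.50. With the asymmetric shell the
threshold crossing lands within a fraction of a millimeter of the true
surface for SUVmax between roughly 10 and 50, and within ~2 mm (erosion)
at the lowest admissible SUVmax — so the auto-contour recovers the truth
well without being trivially identical to it, and the 20%-of-max and
absolute-2.5 criteria always select nested regions. The plateau requires
`min(tumor_radius, tumor_length / 2) > 4` mm for the realized SUVmax to
reach the nominal value.

Noise is additive Gaussian, clipped to physical ranges: SUV sd 0.2 (chosen
so thresholding stays stable: the background-to-threshold gap is at least
7 sd) and 15 HU on CT. The spec seed fully determines the phantom.

**Voxel membership** is by voxel center: a voxel belongs to a shape iff its
center satisfies the shape inequality, with the center of voxel (i, j, k)
at ((i-0.5) sx, (j-0.5) sy, (k-0.5) sz). Sub-voxel perturbations are
realized by shifting the *analytic* shape before voxelization, never by
resampling a mask, so ground truth carries no interpolation artifacts and
shifts divisible by the spacing reproduce exact lattice translations
(a (3, 4, 0) mm shift on a 1 mm in-plane grid gives a 3D vector of
exactly 5 mm).

## Contour variants and the cohort

Each patient carries three variants with recorded perturbations: a rigid
COM shift per axis, a symmetric cranio-caudal length change, a radius
change, and (for GTV_PET-reg) a smooth sinusoidal axis bend standing in
for residual deformable-registration error. Zero perturbation reproduces
the truth mask exactly.

The default cohort is 32/24/16 patients with upper/middle/distal tumors
(groups A/B/C; 72 total). Per-patient tumor SUVmax is log-normal
(meanlog log 11, sdlog 0.5) truncated to [3.21, 49.50] — median near 11
and mean near 13 — and lengths/radii are normal draws (55 +- 14 mm,
12 +- 1.8 mm) clipped to plausible clinical ranges and to the grid. Every
draw satisfies the SUVmax >= 2 enrollment rule by construction of the
truncation range.

Perturbation scales are the one genuinely free choice: the source design
reports only summary tables of the resulting differences, not their
generating distribution. Defaults are therefore calibrated, not derived:
per-axis shift SDs (1.3, 1.7, 2.6) mm, PET-ref length bias +3 mm (SD
4 mm), radius SD 0.8 mm, half-normal deformation amplitude (SD 1.1 mm),
with group multipliers A 0.6 / B 1.0 / C 2.0 so distal tumors — subject to
peristalsis, respiration and cardiac motion — are systematically more
displaced. The calibration target, fixed before the defaults were frozen,
was a cohort-level median conformity index near 0.70 with mm-scale mean 3D
vectors that grow from group A to group C; the acceptance checks verify
the realized cohort against that target, and the distributions remain
fully configurable. Drawn perturbations are clamped so every variant stays
on-grid and non-degenerate; the clamp is inert at the default grid size
and the recorded (clamped) values are exactly what was applied.

A single global seed expands into per-patient substreams keyed by a hash
of the patient id, so enlarging a cohort never reshuffles existing
patients.

## Delineation rules

**SUV threshold.** The operator's workflow is an ROI sphere dragged over
the lesion; SUVmax is therefore taken *within the sphere*, not globally.
The two stated criteria (absolute SUV 2.5; 20% of SUVmax) are combined as
a single threshold `max(2.5, 0.20 * SUVmax)` — one contour, with both
criteria acting as floors. Because their intended combination is not
standardized, modes applying either criterion alone are exposed as well.
The comparison is inclusive (SUV >= T), which is bit-stable under exact
ties. An ROI SUVmax below 2 signals an enrollment-failure condition; an
empty contour is a warning, not an error. Heart repair is organ-mask
subtraction: the heart boundary is supplied as a CT-derived structure and
removed from the SUV contour.

**CT wall rule.** The clinical rule — keep disease where wall thickness
exceeds 5 mm or non-gas wall diameter exceeds 10 mm under a 400/40 HU
mediastinal window — is written for a human observer, so the operator here
is an explicit surrogate built for phantom testing. Per axial slice,
soft-tissue voxels (HU strictly inside the window) connected to the
esophageal axis point are segmented (2D connected components); wall
thickness is estimated as the smallest per-sector outer radius minus the
innermost tissue radius, and the diameter as the largest outer extent
through the axis, both with a full-width convention (one in-plane voxel
added to center-to-center distances). "Diameter without gas" is read as
the outer diameter of the tissue cross-section including a collapsed
lumen: an annular 4 mm wall with a 12 mm outer diameter is kept by the
diameter criterion while failing the thickness criterion, and the normal
esophagus (9 mm outer diameter, 2.5 mm wall) fails both.

## Metrics

All comparisons require one grid (a nearest-neighbor resampling helper is
provided, preserving binarity). COM is the unweighted mean of member-voxel
centers — contours, not intensity images, are compared. For masks A, B:

* per-axis displacement (A minus B) and `V = (dx^2 + dy^2 + dz^2)^(1/2)`;
* `CI = |A∩B| / |A∪B|` (Jaccard), `DI(A in B) = |A∩B| / |A|` in both
  orders, and Dice, which satisfy `CI = Dice / (2 - Dice)` and
  `CI = 1 / (1/DI_AinB + 1/DI_BinA - 1)` — asserted to 1e-12 in tests;
* symmetric Hausdorff distance over member-voxel centers. External voxels
  are matched against the other mask's 6-connected surface voxels, which
  is exact: the member voxel nearest to an external point always has a
  non-member 6-neighbor;
* volume (voxel count x voxel volume, cm^3); cranio-caudal length as
  occupied-slice extent, (max - min occupied slice + 1) x thickness,
  matching the clinical length reading; maximum transverse diameter as the
  largest in-plane distance between member-voxel centers on any axial
  slice plus one in-plane voxel (a Feret-style full-width convention —
  the on-screen measurement procedure is not standardized, so the
  convention is stated rather than inferred).

Computations are in mm; volume/length/diameter are reported in cm-based
units to mirror clinical tables. Degenerate inputs are contracts, not
crashes: empty-vs-nonempty comparisons define the empty side's DI as 0
with a warning, two empty masks are an error, and a three-way comparison
flags a pair with an empty member while computing the rest.

## Cohort statistics

Summaries are median, quartiles (linear interpolation between order
statistics — IQR values depend on the quartile method, so it is fixed),
mean and sample SD. Paired comparisons of position, volume, CI and DI use
the Wilcoxon signed-rank test; length and maximum transverse diameter use
the paired t test; CI-vs-V association uses Spearman's rho with mid-ranks
and a t-approximation p-value.

The Wilcoxon implementation drops zero differences, mid-ranks ties, and
switches from an exact p-value to a tie-corrected normal approximation
with continuity correction above n = 25 — mirroring common commercial
statistical-package behavior, with both choices configurable. The exact
path computes the null distribution of the positive-rank sum by
convolution over doubled mid-ranks, which equals full sign-assignment
enumeration (for six uniformly signed differences: p = 2/2^6 = 0.03125)
while remaining valid under ties. Monte-Carlo checks in the test suite
verify type-I error within [0.03, 0.07] at alpha 0.05 over 2000 null
cohorts of n = 30 for both paired tests.

No multiple-testing correction is applied by default — each comparison is
read against its own alpha, as is conventional in this literature — and a
Holm option is available. Groups with a single record yield summaries but
flagged-degenerate tests.

Five tables are emitted per run: (t2) mean +- SD of V per contour pair and
group with Wilcoxon comparisons between pairs; (t3) volume summaries;
(t4) length and maximum transverse diameter with paired-t comparisons;
(t5) CI summaries with Wilcoxon comparisons and Spearman CI-vs-V; (t6) all
six ordered DI entries.

## Pipeline

`run_all()` streams patient by patient (one patient's volumes in memory at
a time): simulate, delineate, compare, accumulate, then drop the volumes.
The planning CT is rendered at the true geometry and GTV_3D comes from the
CT wall rule; the PET is rendered at the GTV_PET-reg-perturbed geometry —
the residual misalignment of a registered diagnostic frame — so
GTV_PET-reg genuinely comes from the SUV auto-contour plus heart repair;
GTV_PET-ref, a manual contour by definition, is the recorded analytic
variant. An `analytic` mode uses all three recorded variants instead,
which is the configuration in which zero perturbation provably yields
CI = 1 everywhere.

Per-patient masks, the manifest (with applied perturbations, observed
SUVmax, effective thresholds and voxel counts), per-patient metrics, all
tables and test results, the resolved configuration and a config-hash log
are written on every run; the full CT/PET volumes are written only on
request, since 144 noisy volumes cost roughly a gigabyte and minutes of
compression without adding information beyond the masks and manifest.
Identical configuration and seed reproduce byte-identical outputs.

## Problem sizes and what the tests show

The test suite exercises: metric agreement with naive voxel-enumeration
oracles on 200 random mask pairs (grids up to 20^3); the CI/DI/Dice
identity chain on 1000 random pairs; COM-shift recovery within half a
voxel diagonal over 100 random sub-voxel shifts; the threshold rule across
the SUVmax range with nesting and monotonicity; statistical calibration as
above; and one full default 72-patient end-to-end run, which completes in
a few minutes on one CPU and is checked against the calibrated median-CI
target of 0.70 +- 0.05. Unit tests run on compact grids (about
48 x 48 x 64 at 1.5 x 1.5 x 3 mm) chosen so every invariant is exercised
at interactive speed.

Passing these tests shows that the geometry, rules and statistics do what
they claim on phantoms whose truth is known. It does not validate the
rules on clinical images: the phantom has no anatomical texture, no
partial-volume or PET point-spread blur, no respiratory (4D) motion, and
its perturbation distributions are calibrated summaries, not measurements
of any clinic. Deformable registration itself is out of scope — the
pipeline models only a *pre-registered* PET frame with configurable
residual misalignment — and inter-observer variability is not modeled.
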