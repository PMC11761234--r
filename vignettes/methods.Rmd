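---
title: "Quantifying 3D soft-tissue facial asymmetry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D soft-tissue facial asymmetry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(faceasym)
```

## The measurement problem

A face scanned as a triangulated 3D surface is never perfectly
bilaterally symmetric. Clinically one wants a *regional, graded* answer:
which parts of the face are asymmetric, along which axis, and how badly.
This package implements two complementary answers and the statistics to
compare them:

1. **Wireframe template analysis.** Fifteen spatial angles, each defined
   by an ordered triplet of named soft-tissue landmarks, are measured on
   the left and on the right side. Their relative difference, the *Angle
   Asymmetry Index*, is graded per facial region and axis.
2. **Mirroring-and-overlapping analysis.** The surface is reflected
   across the midsagittal plane, the mirror copy is rigidly best-fitted
   back onto the original, and the residual point-to-surface deviations
   are summarised per region (root-mean-square error, RMSE, and maximum
   facial misalignment, MFM). This is the reference ("gold standard")
   method the template is judged against.

All coordinates are millimetres in a normalized frame: X transverse
(anatomical left positive), Y vertical (superior positive), Z
anteroposterior (anterior positive).

## Pose normalization

Both methods require a standard pose. `frankfort_pose()` builds it from
four landmarks: the transverse axis is the unit vector from right to
left tragion, the vertical axis is the component of (exocanthion
midpoint − tragion midpoint) orthogonal to it, the third axis is their
cross product, and the tragion midpoint becomes the origin. This is a
soft-tissue surrogate of a skull-based horizontal-plane alignment: it
uses only landmarks available on a surface scan, and every analysis in
the package poses its input through it, so results are invariant under
rigid motion of the raw scan.

## The wireframe template

`angular_parameters()` lists the fifteen (region, axis) angle triplets
over a vocabulary of ten bilateral landmark pairs (tragion `Tr`, helix
`He`, zygion `Zg`, gonion `Go`, cheilion `Ch`, subalare `Sal`,
stomion-level point `Stb`, alar point `As`, mental tubercle `Mt`,
exocanthion `Ex`) and three midline landmarks (menton `Me`, gnathion
`Gn`, labrale inferius `Li`). Two triplets serve two table rows each
(`Tr-Zg-Go`, `Me-Go-Mt`); they are computed once and referenced twice.

For each triplet the full 3D angle at the middle landmark is measured on
both sides and the Angle Asymmetry Index is

\[ \mathrm{AAI} = \frac{|R - L|}{L} \times 100\% , \]

with the left angle as denominator by convention. Severity is graded on
half-open bands: mild below 1%, moderate in [1%, 3%), severe at or above
3%. A region is mild only when all three of its axis grades are mild;
otherwise it takes the worst axis grade (`aggregate_region()`).

```{r}
case <- generate_base_face(seed = 1)
res <- evaluate_template(case$landmarks)
res
wireframe_region_grades(res)
```

## The mirroring-and-overlapping pipeline

`run_mirror_analysis()` chains pose normalization, `mirror_mesh()`
(X-negation with winding flip), `best_fit_align()` and
`compute_deviation()`:

* The best fit is a deterministic *trimmed* iterative-closest-point
  alignment: exact nearest-vertex correspondences, the worst 10% of
  matches dropped, a closed-form Kabsch/SVD rigid update per iteration,
  convergence at 1e-6 mm RMS change, at most 100 iterations. Trimming
  matters because the asymmetric parts are exactly what must *not* drive
  the alignment.
* Deviations are point-to-*surface* (closest point on any triangle, not
  closest vertex), signed by the outward vertex normal, and decomposed
  into X/Y/Z components.

Per region the summary reports overall and per-axis RMSE and MFM, graded
under three deviation criteria: criterion 1 on RMSE (0.5 / 1 mm),
criterion 2 on MFM (3 / 6 mm), criterion 3 on MFM (1 / 2 mm); all bands
half-open, and the per-region aggregate follows the same all-mild rule
as the template.

## Regions of interest

Five regions are graded: labial, mandibular angle, cheek, chin, and
articular. Their anatomical boundaries (grooves, bone edges, a
"fan-shaped" area around the gonion) have no closed form on a smooth
soft-tissue surface, so each is operationalized as landmark-level
thresholds in the normalized frame — e.g. the chin is the slab between
the mentolabial-groove level (midpoint of the `Li` and `Gn` heights) and
12 mm below menton, within the mental-tubercle half-width plus a 5 mm
margin. Every threshold is a named, documented default in
`roi_config()` and can be changed without touching code. Lateral extents
of bilateral pairs use the mean *absolute* X of the pair: averaging
signed coordinates of a mirrored pair would cancel to zero.

## Concordance statistics

Recognition is defined as a moderate-or-severe grade. For two methods
with recognition rates $r_1, r_2$ over the same subjects, the
consistency rate is $\min(r_1, r_2)/\max(r_1, r_2) \times 100\%$,
computed on exact rationals and only rounded (half-up, one decimal) for
display. Region-level tables append the average of the exact per-region
rates. `consistency_from_counts()` accepts bare recognition counts, so
published tables can be replayed without the underlying scans;
`reference_recognition_counts()` ships the counts of a 24-patient
reference study for exactly that purpose. `cohen_kappa()` provides the
repeatability statistic, with the constant-rater edge case (chance
agreement 1) defined as 1 for perfect agreement and 0 otherwise.

```{r}
consistency_from_counts(reference_recognition_counts("overall", 3))
```

## The synthetic-face generator

Real scan datasets are rarely redistributable, so validation uses an
analytic generator:

* `generate_base_face()` builds a height field $z = f(x, y)$ of four
  blended Gaussian domes (facial mass, nose, chin, lip bulge) on a grid
  that is *exactly* symmetrized about $X = 0$, at 48×48 vertices by
  default. Bilateral landmarks are planted as exact mirror pairs on the
  analytic surface; the exocanthion X position is solved so the pose
  transform of a base face is the identity. A seeded ±4% variation of
  the dome amplitudes yields distinct but equally symmetric subjects.
  Every base face is therefore a machine-precision null case for both
  pipelines.
* `apply_asymmetry()` plants right-side-only deformations:
  `surface_bump` adds a C¹ compact-support cosine bump **along the local
  outward surface normal** — an axis-aligned push would be foreshortened
  by the surface inclination, whereas the along-normal bump makes the
  measured MFM equal the planted height; `landmark_shift` displaces the
  region's template landmark along a chosen axis, which perturbs the
  region's angles analytically. `calibrate_shift()` root-finds the shift
  for a target AAI.
* `generate_cohort()` draws per-subject seeds and per-region axes,
  magnitudes and bump heights from one seed, so cohorts are bit
  reproducible.

```{r}
bumped <- apply_asymmetry(
  case, asymmetry_spec("cheek", "X", 0, mode = "surface_bump", bump_mm = 2)
)
mr <- run_mirror_analysis(bumped$mesh, bumped$landmarks, criterion = 3)
subset(mr$analysis$summary, axis == "overall")
```

## Problem sizes and limitations

The default 48×48 grid (2304 vertices) keeps a full mirror analysis
around a second on commodity hardware while leaving each region over a
hundred vertices; it is a package default, not a property of the
method, and scales with the `resolution` argument. Known limitations:

* The pose surrogate depends on four landmarks; gross placement errors
  rotate the entire analysis.
* Trimmed point-to-point ICP assumes the asymmetric fraction of the
  surface is modest; faces asymmetric over most of their area could bias
  the best fit.
* The region thresholds are surrogates for anatomical boundaries; on
  real scans they should be reviewed against the individual anatomy.
* The generator's faces are smooth analytic surfaces — ideal for
  validating the measurement chain, not a statistical model of human
  facial variation.
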