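---
title: "Radiographic hip measurements and reader reliability: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiographic hip measurements and reader reliability: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipmetrics)
```

## The measurement problem

Hip dysplasia in skeletally mature patients is assessed on anterior-posterior
(AP) pelvic radiographs through a small set of standardized measurements. All
of them are taken relative to the *inter-ischial reference line*, the line
joining the most inferior points of the two ischial tuberosities, so that
radiograph tilt does not bias the angles:

- **LCEA** (lateral center edge angle of Wiberg): at the femoral-head center
  (CFH), the angle between the perpendicular to the reference line and the
  ray to the lateral extent of the acetabular sourcil. It quantifies lateral
  coverage of the femoral head; small values suggest dysplasia.
- **AIA** (acetabular index angle): the angle between the
  reference-line-parallel through the medial sourcil and the medial-to-lateral
  sourcil line. It quantifies the inclination of the weight-bearing roof.
- **FOI** (foramen obturator index): the ratio of the maximum right to
  maximum left obturator-foramen width, both measured parallel to the
  reference line; a check on pelvic rotation (about 1 when unrotated).

The CFH is not a landmark anyone can point at: it is obtained by fitting a
circle to points on the femoral-head contour. `hipmetrics` implements this
measurement chain from either explicit landmarks or per-structure binary
segmentation masks, together with the statistical machinery used to judge
such readers: Bland-Altman agreement, mixed-model variance components,
repeatability coefficients and agreement-study sample sizes.

## Conventions

**Coordinates.** Image raster coordinates: `x` is the column, `y` the row,
`y` increasing downward, pixel centers at integer positions. "Superior" is
towards smaller `y` *relative to the reference line's frame*, not the image
axis; every angle is computed in that frame, so the whole geometry is
invariant to rigid motion of the scene (tested to 1e-9 degrees).

**Laterality.** By radiographic display convention the patient's right hip
appears on the image left. A `laterality_convention` flag on the landmark
set switches this. All medial/lateral logic is derived from the side and the
reference frame, never from the raw sign of `x`.

**Angle signs.** LCEA is positive when the lateral sourcil lies lateral to
the superior perpendicular through the CFH and negative when medial, so a
dysplastic, uncovered head yields small or negative values. AIA is positive
when the roof slopes upward from medial to lateral and negative when it
slopes downward — negative AIA values occur in real series and must be
representable. Degenerate-but-plausible anatomy (a sourcil inferior to the
CFH) produces a value plus a warning flag rather than an error: an automated
reader must still report on abnormal hips. Only truly undefined geometry
(coincident points, collinear contours) raises errors, which name the
offending landmarks.

## Numerical geometry

**Circle fit.** The femoral-head circle uses the algebraic least-squares
(Kåsa) parameterization: minimising the residuals of
$x^2 + y^2 + Dx + Ey + F$ is a linear problem solved in closed form by QR.
It is exact on noiseless circles, deterministic, and on realistic contour
noise agrees with a brute-force grid search over center and radius to within
the grid resolution (a property the test suite checks). An optional
Gauss-Newton geometric refinement is available behind `refine = TRUE`; it is
off by default because bit-for-bit reproducibility of repeated runs is a
design requirement.

**Width profiles.** Foramen widths are measured on 13 equidistant lines
parallel to the reference line. The lines span the foramen's own
perpendicular extent, endpoints included — a parameter-free placement that
makes the profile reproducible across images. On each line the width is the
outermost-crossing (caliper) distance, matching how a clinician lays a ruler
across the foramen; interior concavities do not subtract from the width.

**Mask extraction.** Mask boundaries are traced at sub-pixel resolution by
marching squares on the zero-padded raster (the 0.5 iso-contour), which is
what makes the circle fit accurate to a fraction of a pixel. Tuberosity and
sourcil landmarks, in contrast, are integer-pixel extrema — clinically they
are single annotated pixels. The tuberosity is the most inferior foreground
pixel per side (ties resolved towards the midline); sourcil extents are
extremal *along the reference direction*, so a tilted radiograph selects the
same anatomical pixels once the reference line is known. Among pixels within
half a pixel of the extremal position the one with the median perpendicular
offset is taken, which centers the landmark inside the segmented band's
thickness. When a mask has several connected components the largest is used
and a flag records the fact.

## The synthetic phantom

Clinical radiographs cannot ship with a package, so validation rests on a
phantom with closed-form ground truth. `phantom_spec()` fixes true LCEA and
AIA per side, true FOI, and the scene geometry; `landmarks_from_truth()`
inverts the measurement definitions to place the landmarks (e.g. the lateral
sourcil sits on the ray at exactly the true LCEA from the superior
perpendicular), so `measure_hips()` must return the spec values exactly —
the round trip is tested to 1e-9 degrees, including under scene rotation.
`rasterize_phantom()` draws the same geometry as binary masks: filled discs
for the heads, a thin (0.7 px half-width) capsule for each sourcil, filled
ellipses for the foramina, and ischial blobs whose most inferior points are
the tuberosity landmarks. The sourcil is drawn deliberately thin so that
integer-pixel extremal extraction lands within about half a pixel of the
true endpoints; with the default geometry (head radius 9.5% of the image
width, sourcil chord 1.35 head radii) the full mask pipeline recovers truth
within 0.5 degrees and 0.02 FOI at 1024 px, and the error shrinks with
resolution.

Batch truth values are drawn from distributions matching an adult referral
population: LCEA ~ N(25.4, 7.0²), AIA ~ N(4.7, 5.7²) (truncated to feasible
geometry), FOI ~ N(1, 0.05²). An optional smooth boundary jitter (low-order
Fourier perturbation of each shape outline, amplitude in pixels, seeded)
emulates segmentation raggedness.

What the phantom does *not* emulate: bone texture, overlapping projections,
exposure variation, or systematic segmentation failure modes of a trained
network. Passing the phantom suite therefore demonstrates the correctness of
the geometry given faithful masks, not the performance of any particular
segmentation model on clinical images.

## The reader-study simulator

`simulate_reader_study()` mirrors a reliability study in which every reader
measures every patient once and a small subset (default 5 patients) is
re-read by everyone on two further occasions:

$$y_{prk} = \mu + X_p\beta + a_p + b_r + c_{pk} + \varepsilon_{prk}$$

with independent normal patient, reader, occasion and residual components.
The occasion effect $c_{pk}$ is attached to the patient-by-occasion cell and
*shared across readers*: the re-read radiographs are re-presented to all
readers, and this sharing is precisely what makes a separate repeat variance
identifiable next to the residual in this design. Patient covariates (age,
sex, FOI, exposure noise) are drawn once per patient and enter through fixed
coefficients, zero by default. A single seed drives all randomness.

## Statistics

**Bland-Altman.** Bias is the mean difference; the 95% limits of agreement
are bias ± 1.96·SD. The multiplier is the normal quantile 1.96, not a t
quantile — consistent with the repeatability-coefficient constant
2.77 ≈ 1.96·√2 used throughout this literature. The bias CI is the usual t
interval. For the LoA two CI constructions are provided: the classic
approximate interval ± t·s·√(3/n), and the default *MOVER* interval, which
combines the t interval for the mean with the χ² interval for the SD and is
asymmetric (longer outward arm), as published agreement tables show.
Incomplete pairs — images one method failed to read — are excluded and
counted, never imputed.

**Variance components.** `fit_variance_components()` fits the simulator's
model by REML through `lme4::lmer` with random intercepts for patient,
reader and patient-occasion. The optimizer is bounded BOBYQA on the
variance-ratio scale tightened to `rhoend = 2e-9`, at which point balanced
designs reproduce the closed-form ANOVA method-of-moments components to
1e-6 (a test asserts this). Non-negativity is inherent to the
parameterization; profile-likelihood CIs (on the SD scale, squared to
variances) are available with `ci = TRUE`. With no re-read occasions the
repeat variance is structurally unidentifiable and is fixed at zero with a
flag rather than silently estimated.

**Repeatability coefficients.** RC = 2.77 × within-subject SD: same-reader
RC uses the residual variance alone; different-reader RC adds the reader
variance. The constant is the literal 2.77 conventional in this field (using
1.96·√2 = 2.7719 shifts some published values by 0.01 at two decimals).
Rounding happens only at presentation.

**Sample size.** `ba_sample_size()` finds the smallest n for which both 95%
LoA confidence bounds fall inside the clinical agreement band ±δ with the
requested probability. The LoA confidence bound uses the approximate
standard error s·√(3/n) with the two-sided t quantile; conditional on the
sample SD both containment conditions are normal in the sample mean
(noncentral-t per side), and the joint probability is integrated exactly
over the χ distribution of the sample SD. Among the standard variants of
this calculation (exact vs approximate SE, one- vs two-sided quantile,
Bonferroni vs exact joint probability) this is the one whose answers agree
with published agreement-study designs, e.g. n = 176 at sd = 2.1°, δ = 5°,
power 80%; a Monte-Carlo simulation of the containment probability at the
returned n is part of the test suite. The search ascends from n = 3, so an
arbitrarily generous δ returns the minimal meaningful study.

```{r}
ba_sample_size(sd = 2.1, delta = 5, alpha = 0.05, power = 0.80)
patients_from_measurements(176, hips_per_patient = 2, n_triple_read_patients = 5)
repeatability_coefficients(17.80, 11.88)
```

**Multiple testing.** None is applied; the package reports estimates and
intervals, not hypothesis-test families.

## Problem sizes in the test suite

The suite validates the statistics at sizes chosen to balance sampling error
against desk-scale runtimes: the parameter-recovery experiment uses 100
simulated studies of 400 patients × 5 readers (checking that each true
component falls inside its own 95% profile CI at least 90 times), LoA
coverage uses 10⁵ simulated differences, the Monte-Carlo power check 2×10⁴
studies, and the raster pipeline is checked on batches of 6–10 phantoms at
512–2048 px. All seeds are fixed in the tests.

## Known limitations

- Reader effects are modelled as crossed with patients but not with side;
  each metric/side is analysed independently, as per-side reporting does.
- The repeat effect is occasion-shared (see above); designs in which each
  reader re-reads independently would need a reader-nested repeat term.
- Only five readers' worth of information is typically available for the
  reader variance, so its profile CI is wide; that is a property of such
  designs, not of the estimator.
- The phantom's sourcil is a thin band; segmentations that are several
  pixels thick will localise the extents to the band's ends with
  correspondingly larger angle uncertainty.
- Masks are the input contract: the package deliberately contains no
  segmentation model and no intensity-based image processing.
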