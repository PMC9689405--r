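# hipmetrics

Measurement core of an automated reader of anterior-posterior (AP) pelvic
radiographs for hip-dysplasia workup, plus the statistics used to judge the
reliability of such readers — human or algorithmic.

Radiographic assessment of hip dysplasia rests on a few standardized
measurements taken relative to the *inter-ischial reference line* (the line
joining the most inferior points of the ischial tuberosities):

- **LCEA**, the lateral center edge angle of Wiberg: the angle at the
  femoral-head center (CFH) between the perpendicular to the reference line
  and the ray to the lateral acetabular sourcil. The CFH is the center of a
  least-squares circle fitted to the femoral-head contour.
- **AIA**, the acetabular index angle: the angle between the
  reference-line-parallel through the medial sourcil and the
  medial-to-lateral sourcil line.
- **FOI**, the foramen obturator index: the ratio of right to left maximum
  obturator-foramen widths, each the maximum over 13 equidistant lines
  parallel to the reference line — a pelvic-rotation check.

`hipmetrics` computes these from landmark files (JSON) or per-structure
binary segmentation masks (PNG), deterministically (identical input gives
bit-identical output). Because clinical radiographs cannot be redistributed,
the package ships a synthetic pelvic phantom with closed-form ground truth
and a multi-reader study simulator with patient/reader/repeat variance
components, so every stage is testable end to end. The reliability toolbox
implements Bland-Altman limits of agreement with approximate and MOVER
confidence intervals, REML variance components (via `lme4`), repeatability
and reproducibility coefficients (RC = 2.77 × within-subject SD), and
Bland-Altman agreement sample-size calculation.

## Worked example

```r
library(hipmetrics)

## a phantom with known truth: LCEA 25.4/25.9, AIA 4.7/4.0, FOI 1
spec <- phantom_spec(seed = 1)
m <- measure_hips(landmarks_from_truth(spec))
m
#> <hip_measurements> phantom_seed1
#>   LCEA  right   25.400  left   25.900 deg
#>   AIA   right    4.700  left    4.000 deg
#>   Foramen width right 112.64  left 112.64 px;  FOI 1.0000

## the same phantom through rasterized masks (the segmentation-style input)
measure_hips_from_masks(rasterize_phantom(spec))$lcea
#>    right     left
#> 25.37845 25.98941

## reliability: repeatability coefficients from mixed-model variance components
repeatability_coefficients(17.80, 11.88)
#> RC same patient, same reader:      11.69
#> RC same patient, different reader: 15.09

## agreement-study design: measurements needed so that both 95% LoA
## confidence bounds fall within +/-5 degrees, assuming SD 2.1 degrees
ba_sample_size(sd = 2.1, delta = 5, alpha = 0.05, power = 0.80)
#> [1] 176
patients_from_measurements(176, hips_per_patient = 2, n_triple_read_patients = 5)
#> [1] 78
```

The first block shows the inverse-geometry guarantee: landmarks are placed
so the measured angles equal the spec exactly. The mask route re-derives all
landmarks from rasterized structures and recovers the truth to a few tenths
of a degree at 1024 px. The RC output reads: two measurements of the same
patient by the same reader are expected to differ by less than 11.69° in 95%
of cases, rising to 15.09° between readers.

A command-line front-end is installed with the package
(`system.file("cli", "hipread", package = "hipmetrics")`) with subcommands
`measure`, `double-read`, `phantom`, `simulate-readers`, `agree`, `varcomp`,
`samplesize` and `summarize`.

## Package layout

- `R/geometry.R` — reference line, Kåsa circle fit, LCEA/AIA, width profiles
- `R/landmarks.R` — landmark container, measurement engine, JSON I/O
- `R/masks.R` — mask I/O and landmark extraction (sub-pixel boundaries)
- `R/phantom.R` — phantom spec, inverse geometry, rasterization
- `R/simulate.R` — multi-reader study simulator
- `R/agreement.R`, `R/varcomp.R`, `R/samplesize.R` — reliability statistics
- `R/cli.R` — batch orchestration, reports, CSV/JSON round-trip I/O
- `vignettes/hip-measurement-reliability.Rmd` — models, conventions and
  design choices in full
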