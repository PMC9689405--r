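Package: hipmetrics
Title: Radiographic Hip Measurements and Reader Reliability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core of an automated reader of anterior-posterior
    pelvic radiographs for hip dysplasia workup. Turns anatomical landmarks or
    per-structure segmentation masks into the standard dysplasia measurements:
    lateral center edge angle of Wiberg (LCEA), acetabular index angle (AIA),
    obturator foramen widths and the foramen obturator index (FOI), all taken
    relative to the inter-ischial reference line, with the femoral head center
    obtained by least-squares circle fitting. Includes a synthetic pelvic
    phantom with closed-form ground truth, a multi-reader measurement-study
    simulator with patient/reader/repeat variance components, and the
    reliability statistics used to evaluate such readers: Bland-Altman limits
    of agreement with approximate and MOVER confidence intervals, REML variance
    components, repeatability and reproducibility coefficients, and
    Bland-Altman sample-size calculation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    lme4,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
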