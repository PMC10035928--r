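Package: spinetopo
Title: Spinal Column Profiles from Surface Topography Landmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Landmark-based comparison of internal spinal column shape with
    skin-surface marker profiles, for studies relating back-surface topography
    to the underlying vertebral column. Builds anatomical coordinate frames
    from pelvic and lumbar markers, rigidly aligns surface-scan marker sets to
    the MRI frame, fits seventh-order polynomial profiles to sagittal and
    coronal landmark series, resamples them at fixed cephalo-caudal intervals,
    computes plane parametric-curve curvature, and quantifies profile
    agreement via root-mean-square distance, two-sample Kolmogorov-Smirnov
    tests, Pearson correlation with body mass index, age and gender, and
    intraclass correlation reliability. Includes a synthetic cohort generator
    emulating the measurement structure of paired MRI/surface-scan studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
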