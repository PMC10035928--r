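# spinetopo

Landmark-based comparison of internal spinal column shape with skin-surface
marker profiles.

## What this is for

Surface topography of the back — skin markers captured by a 3D surface
scanner — is a cheap, radiation-free alternative to radiographic spinal
imaging, *if* markers placed over the palpable spinous processes track the
underlying bone. `spinetopo` implements the analysis pipeline for paired
MRI / surface-scan landmark studies that test this:

* **Phase 1 — skin vs bone (within MRI):** the spinal column profile (SCP,
  from MRI spinous-process selections) is compared with the fiducial marker
  profile (FMP, from skin capsules visible in MRI) in the sagittal and
  coronal planes, via profile distance and curvature similarity, and the
  offsets are related to BMI, age and gender.
* **Phase 2 — scanner vs MRI (same skin markers):** the surface-scan marker
  profile (3MP) is rigidly aligned to the MRI frame and compared with the
  FMP via the sampled coordinate distributions, probing how well posture is
  reproduced across scanners.

The audience is biomechanics and spine researchers working with labelled
anatomical landmarks (vertebral levels T1–L5 plus pelvic PSIS markers).

## Method core

Each planar landmark series (cephalo-caudal coordinate z against the
antero-posterior or lateral coordinate v) is reduced to a degree-7
polynomial fitted by least squares in a scaled variable, then resampled at
20 mm stations. At each station the plane parametric-curve curvature

    k = |x'y'' - y'x''| / (x'^2 + y'^2)^(3/2)

is computed by finite differences on the sampled sequence. Profile
agreement is quantified by the matched-station root-mean-square distance
(RMSD; overall and per thoracic/lumbar region), two-sample
Kolmogorov–Smirnov tests (exact small-sample mode; curvature samples for
SCP-vs-FMP, coordinate samples for FMP-vs-3MP, alpha = 0.05), a Pearson
correlation matrix against BMI/age/gender, and ICC(2,1) observer
reliability. A synthetic cohort generator reproduces the measurement
structure (BMI-dependent posterior adipose offset, left-lateral soft-tissue
bias, smooth posture misalignment between modalities, duplicate observer
sessions) so the whole pipeline is testable without clinical data. The
methods vignette (`vignettes/spinetopo-methods.Rmd`) documents every model
and parameter.

## Worked example

```r
library(spinetopo)

cfg     <- generator_config(n_subjects = 50, seed = 1)  # study conditions
cohort  <- generate_cohort(cfg)                         # landmarks + demographics
results <- analyze_cohort(cohort)
print(results)
```

```
<cohort_results> 50 subjects (50 with scans)
  SCP vs FMP sagittal RMSD: 22.14 +/- 3.58 mm
  SCP vs FMP coronal RMSD: 5.59 +/- 0.68 mm
  KS nonsignificant (SCP_vs_FMP, sagittal): 100%
  KS nonsignificant (SCP_vs_FMP, coronal): 78%
  KS nonsignificant (FMP_vs_3MP, sagittal): 100%
  KS nonsignificant (FMP_vs_3MP, coronal): 62%
```

Reading this: skin fiducials sit ~22 mm posterior to the spinous processes
(the subcutaneous layer), ~6 mm laterally offset; their curvature profiles
are statistically indistinguishable from the bone's for (almost) all
subjects in the sagittal plane and most in the coronal plane; and after
repositioning between scanners the coronal plane — not the sagittal — is
where marker coordinate distributions drift apart. Per-subject rows live in
`results$comparisons`; `results$correlations` holds the Pearson matrix
(e.g. BMI vs overall sagittal RMSD r = 0.66, strong, p < 0.001 under these
conditions); `results$reliability` the per-axis ICCs (all > 0.99, "almost
perfect"). `write_report(results, dir)` writes the per-subject comparison
CSV, correlation CSV, KS summary CSV and a JSON run manifest.

A shell interface with the same surface is available:

```sh
exec/spinetopo simulate --config cfg.yaml --out data/
exec/spinetopo analyze --landmarks data/landmarks.csv \
    --demographics data/demographics.csv --out report/
```

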