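---
title: "Estimating internal spinal column shape from surface-marker profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating internal spinal column shape from surface-marker profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinetopo)
```

## The problem

Back-surface topography is an attractive, radiation-free surrogate for
radiographic spinal imaging: if skin markers placed over the palpable
spinous processes track the underlying bone faithfully, then a surface
scanner can stand in for MRI or X-ray in posture and spinal-curvature
studies. Whether that substitution is justified is an empirical question
with two parts:

1. How far, and how consistently, does the *skin* profile sit from the
   *bone* profile, and what drives that offset (subcutaneous adipose
   thickness, hence BMI; lateral soft-tissue distortion in the lying
   posture)?
2. Does a surface-scan measurement of the same skin markers reproduce the
   MRI measurement of those markers, given that the subject must be
   repositioned between scanners?

`spinetopo` implements the full analysis pipeline for such paired
MRI/surface-scan landmark studies, together with a synthetic cohort
generator that emulates the measurement structure, so every stage is
testable without access to clinical data.

## Data model and coordinate conventions

All inputs are labelled 3D landmarks: per subject, three sources —
MRI spinous-process selections (the internal chain, T1–L5), MRI skin
fiducials (capsules adhered over the spinous processes), and surface-scan
markers (stickers at the same sites) — plus demographics (gender, age,
height, weight). One coordinate convention is enforced at I/O: +z cephalad,
+y posterior, +x subject-left, millimetres.

The anatomical frame mirrors the lateral-lying imaging setup: origin at
the L1 marker; the antero-posterior axis is the substrate normal; the
cephalo-caudal axis points from the midpoint of the posterior superior
iliac spine (PSIS) markers toward L1, projected into the substrate plane;
the lateral axis completes a right-handed triad. Scan-marker sets are
brought into the MRI frame by least-squares rigid superposition (Kabsch /
orthogonal Procrustes without scaling) over shared labels. If the shared
labels are collinear the rotation about that line is unconstrained; we take
the minimal rotation mapping the scan line direction onto the reference
direction and warn.

## Profiles, curvature and distance

Each projected planar series (sagittal: z vs antero-posterior; coronal:
z vs lateral) is reduced to a degree-7 polynomial fitted by ordinary least
squares in a centred/scaled z variable (the z range mapped to [-1, 1] for
conditioning). The fit RMSE against the original points is reported per
profile. Profiles are resampled at 20 mm stations anchored at the most
cephalad fitted point, stepping caudally while inside the fitted domain;
when two profiles are compared their shared grid is anchored at the shared
most-cephalad domain point so matched-station metrics are well defined.

Curvature at each station uses the plane parametric-curve formula

$$k = \frac{|x'y'' - y'x''|}{(x'^2 + y'^2)^{3/2}},$$

with derivatives estimated by central finite differences on the sampled
point sequence (one-sided stencils at the two endpoints), taking the point
index as the curve parameter — curvature is independent of
parameterisation. An analytic mode differentiates the fitted polynomial
exactly and serves as the internal reference: the finite-difference error
is second order in the station spacing (about 4% of the curvature scale at
20 mm on a typical kyphotic arc, shrinking fourfold when the spacing
halves). Endpoint (one-sided) curvature values are included in KS samples
by default and can be dropped via `ks_endpoints = FALSE`.

Profile distance is the matched-station difference of the profile value at
identical stations — not a closest-point distance; RMSD is the
root-mean-square of those differences, reported overall and separately for
the thoracic and lumbar regions. The regional boundary is the T12–L1
midpoint; a station exactly on the boundary counts as thoracic. For
coronal profiles the signed lateral statistics are also reported
(positive = fiducial left of the spine; exact zeros count as not-left).

## Statistics

* **Two-sample KS tests** compare SCP-vs-FMP *curvature* samples and
  FMP-vs-3MP *coordinate* samples (following the two comparison phases).
  The p-value is exact (network algorithm, equivalent to full permutation
  enumeration) whenever `n1*n2 <= 1e4`, asymptotic (Kolmogorov distribution
  with effective size `n1*n2/(n1+n2)`) otherwise. Significance is assessed
  at alpha = 0.05; no multiple-testing correction is applied, and the
  report carries the number of tests run.
* **Pearson correlations** relate the six subject-level RMSD variables to
  BMI, age and gender (coded female = 1, male = 2 — a point-biserial
  correlation in interpretation). Two-sided p-values use the t-distribution
  with n-2 df. Strength bands: |r| >= 0.5 strong, 0.3–0.49 moderate, else
  low. Zero-variance variables are flagged rather than yielding NaN.
* **Reliability** between duplicate observer sessions uses the
  single-measure two-way random-effects ICC. The SPSS-style model/type is
  ambiguous in much of the applied literature; we fix absolute agreement
  ICC(2,1) as the default and expose the consistency form behind
  `type = "consistency"`. ICC > 0.81 is labelled "almost perfect".
* **BMI** = weight/height²; classes underweight (< 18.5), healthy
  (18.5–24.9), overweight (>= 25), with the boundary values 18.5 and 25
  falling upward.

## The synthetic cohort generator

The generator defines the study conditions; it is not a tuning dial. Its
defaults describe a 50-subject healthy adult cohort: BMI 22.82 ± 3.22 kg/m²
(truncated normal on [16, 31] so all three BMI classes occur), age
23.48 ± 2.79 years on [18, 30], an exact even gender split, and
gender-specific heights (1.65/1.78 ± 0.06 m) from which weight is derived.

* **Spine.** A T1–L5 chain with 27 mm thoracic and 33 mm lumbar
  inter-level spacing (~462 mm; the spacing table is configurable — these
  values are standard adult averages). The sagittal shape is a quartic
  polynomial vanishing at both chain ends and at the thoracolumbar
  inflection, whose two free coefficients are solved so the thoracic
  (kyphosis, posterior, default 25 mm) and lumbar (lordosis, anterior,
  default 20 mm) lobe extrema equal their configured amplitudes exactly;
  keeping the smooth shape inside the degree-7 span makes fit-RMSE
  properties analytic. The coronal deviation is a parabolic arc (default
  3 mm). Amplitudes get per-subject multiplicative jitter (relative SD
  0.1). On top of the smooth arcs each level receives independent in-plane
  irregularity of SD 0.8 mm — anatomical level-to-level variation plus
  voxel-selection error. Without it the synthetic curvature sample is
  degenerate (essentially constant within a plane) and the curvature KS
  comparison becomes an all-or-nothing test unlike any real data; 0.8 mm
  also puts the profile fit RMSE in the sub-millimetre range observed in
  MRI landmark studies.
* **Fiducials.** Posterior offset = 1.3 mm + 0.9 mm × BMI + a
  between-subject term (SD 3 mm) + per-level noise (SD 0.5 mm), floored
  just above zero — skin markers are always posterior to bone. The slope
  and intercept place the mean offset at a typical adult BMI in the low
  twenties of millimetres; the between-subject SD was fixed by an a priori
  Fisher-z power calculation so that the BMI–RMSD correlation is strong
  (population r ≈ 0.7) yet not artificially tight. The lateral offset is
  biased subject-left (5.17 ± 2.83 mm, matching the soft-tissue distortion
  reported in lateral lying); because adipose distortion is spatially
  continuous, 95% of its variance rides on a smooth degree-≤2 field along
  the chain and the remainder is per-level placement jitter
  (`lateral_smooth_frac`, set it to 0 for fully independent draws).
* **Scan markers.** Fiducials plus a smooth posture-misalignment field — a
  random degree-≤2 polynomial in z, normalised so its maximum over the
  chain equals the configured amplitude (12 mm coronal, 2 mm sagittal by
  default: repositioning between scanners visibly shifts shoulders and
  hips in the coronal plane, while sagittal posture is reproduced well) —
  plus 0.5 mm isotropic repositioning noise.
* **Reliability subjects.** The first two subjects carry duplicate
  session-2 MRI selections with 0.5 mm isotropic observer noise.

All randomness flows from one master seed through fixed per-subject
streams, so identical configurations give byte-identical cohorts and
adding subjects never perturbs earlier ones.

What the generator deliberately does **not** emulate: articulated
vertebral kinematics (posture misalignment is a smooth field, not a joint
model), BMI-dependent posture sensitivity, breathing artefact, surface
meshes (landmarks only), and any scoliotic deformity. Passing tests
therefore demonstrate that the pipeline recovers the structure this model
encodes — offset–BMI coupling, curvature preservation under smooth
distortion, coronal-plane sensitivity to posture — not that it certifies
any particular clinical dataset.

## Numerical choices and degenerate inputs

* Polynomial fits require at least degree + 2 distinct-z points; duplicate
  z values are an error, not silently averaged.
* Station grids need a domain of at least two intervals; common grids need
  the two domains to overlap by the same margin.
* Exact zeros in signed lateral differences count as not-left; a station
  exactly on the regional boundary counts as thoracic (its defining
  markers are equidistant).
* The sagittal-arc coefficient solver iterates extremum location and a
  2×2 linear solve to machine precision; one-sided zero amplitudes fall
  back to a single full-chain parabola, and both-zero gives a straight
  chain.
* Degenerate cohort tables (zero-variance variables, empty BMI classes)
  produce flagged entries (`note = "zero variance"`, `NA` percent change)
  rather than errors, so a partial report is always written.
* Landmark sets tagged with a non-anatomical frame (raw scanner exports)
  skip the cephalo-caudal monotonicity check, which is only meaningful in
  the anatomical convention.

## Problem sizes used in the tests

The test suite exercises single subjects and cohorts of 4–50 subjects;
the analysis-level recovery checks use 100 seeded 50-subject replicates
for the BMI-slope association, one 50-subject cohort per condition for the
curvature-similarity check, and a five-point posture-amplitude ladder with
two seeds per rung. The KS type-I-error simulation uses 2000 null pairs of
sizes 60 and 53 in exact mode — unequal sizes give the exact null
distribution a rich support whose attainable significance level sits next
to 0.05, so the nominal and attainable levels are comparable.

## Known limitations

* The degree-7 polynomial is a modelling commitment inherited from the
  analysis design, not a claim of optimality; no spline or Gaussian-process
  alternative is offered.
* Curvature is planar; 3D space-curve curvature/torsion is out of scope.
* The rigid scan-to-MRI alignment assumes the marker constellation moved
  rigidly between scanners; genuinely articulated posture change is
  captured only through the smooth misalignment field it leaves behind.
* Generator magnitudes are calibrated to the reported ranges of comparable
  adult cohorts but are not claimed to equal any study's true anatomy —
  per-level offset magnitudes in particular are unobservable in published
  summaries.

## A worked example

```{r example, eval = FALSE}
cfg <- generator_config(n_subjects = 50, seed = 1)
cohort <- generate_cohort(cfg)
results <- analyze_cohort(cohort)
print(results)
write_report(results, "spinetopo-report")
```

See the README for the numbers this prints and how to reproduce the
headline quantities with `scripts/acceptance.R`.
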