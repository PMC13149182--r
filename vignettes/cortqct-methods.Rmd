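---
title: "Methods: cortical bone morphometry, QCT classification and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cortical bone morphometry, QCT classification and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortqct)
```

# Overview

`cortqct` quantifies the cortical shell of an L1-like vertebral body on CT
and evaluates the resulting parameters as discriminators of QCT-defined
osteoporosis. The pipeline has six stages: phantom/cohort generation,
segmentation, morphometry, QCT vBMD measurement and classification, cohort
statistics, and orchestration. This vignette documents the models, the
parameters that matter, the numerical choices, and the limits of what the
synthetic world can establish.

# The phantom model

The imaging stage is validated against digital phantoms rather than patient
scans, which are not available. A phantom is an elliptic cylinder: an outer
ellipse with semi-axes $(a, b)$ (default $18 \times 14$ mm, a nominal adult
L1 cross-section), a cortical shell of construction thickness $t$ between
the outer ellipse and the inner ellipse $(a - t,\, b - t)$, a trabecular
core inside, and soft tissue outside. Default attenuations are 1200 HU
(cortex), 150 HU (trabecular), 40 HU (soft tissue) — deliberately far from
the 250 HU segmentation threshold so that failures indict algorithms, not
scenes. Voxel spacing defaults to $0.7 \times 0.7 \times 1.25$ mm: 1.25 mm
reconstructed slices, and 0.70 mm in-plane for a 512 matrix over a ~360 mm
field of view (the matrix size is standard; the field of view, and hence
the in-plane spacing, is a nominal choice). The body height (25 mm, 20
slices) is an exact multiple of the slice spacing so the analytic volume
$\sum_k \pi\!\left(ab - (a-t_k)(b-t_k)\right)\Delta z$ is comparable to
voxel counts without end-slice bookkeeping. The body axis is offset from
the grid by a fraction of a voxel: exact alignment of voxel centers with
the symmetry axes is an artifact of simulation, not of scanning, and biases
voxel counting.

Partial-volume blur is a separable Gaussian PSF parameterized by FWHM in
mm; noise is additive Gaussian in HU, drawn after blurring, seeded.
Ground-truth masks, per-slice analytic areas and the analytic shell volume
come from the *unblurred* geometry. An optional linear taper thins the
shell toward the endplates to exercise slice-averaging logic; the default
is a uniform shell.

What the phantom does **not** emulate: trabecular texture, posterior
elements and pedicles, osteophytes, endplate curvature, beam hardening, or
scanner reconstruction kernels. A green recovery test therefore establishes
that the measurement chain is geometrically correct at clinical resolution
— not that it would segment real anatomy; the segmentation surrogate is a
stand-in for a proprietary system whose algorithm is not reproducible from
public information.

# Segmentation surrogate

Per slice: bone = HU ≥ threshold (default 250 HU, configurable because no
canonical value exists), closed with a 1-voxel disk; body = hole-filled
bone mask (2D filling, matching the slice-wise measurement logic);
cortical = bone; trabecular = body minus bone. The largest 6-connected 3D
component is retained; a second component above `min_component_voxels` is
rejected, since upstream vertebra labeling is assumed. Empty bone yields a
flagged empty result, not an error. Endplate slices are included; the
morphometry stage offers `slice_trim` to exclude them.

# Morphometry

The four parameters follow the measurement protocol literally:

- **Thickness.** Twelve rays per slice from the body-mask centroid at 30°
  increments (the protocol fixes the count at 12 points per slice but not
  their placement; uniform angular sampling is the neutral choice and
  `n_rays`/`ray_start_angle` are configurable). Per ray, the thickness is
  the outermost contiguous cortical run — robust to interior speckle — with
  the mask sampled bilinearly at 0.07 mm steps and run boundaries refined
  by linear interpolation of the 0.5 crossing. The slice value is the mean
  over rays that hit; slices with fewer than `min_hits_per_slice` hits are
  excluded. The vertebra value is the unweighted mean over slices, as is
  the average area (the protocol averages "all layers" without weights).
- **Area** = cortical voxel count × pixel area per slice, averaged.
- **Volume** = cortical voxel count × voxel volume.
- **Density** = summed cortical HU / cortical volume, honoring the stated
  "total density over total volume" ratio and its HU/mm³ unit label. The
  wording leaves open whether the denominator is the cortical or the whole
  vertebral-body volume; cortical is the default and
  `density_denominator = "body"` exposes the alternative (the choice only
  rescales the parameter and nothing downstream depends on it).

**Accuracy.** On a binary mask the boundary position along a ray is
quantized by up to half a voxel at *each* of the two interfaces, so the
per-ray guarantee is one in-plane spacing (0.7 mm); errors cancel across
the 12 rays, giving half a spacing for the slice mean, which is the
contract the recovery tests and acceptance sweep assert (thickness within
max(0.35 mm, 5%), volume and area within 5%, measured-vs-true slope within
1 ± 0.1 across 1–4 mm shells). Note also that for an elliptical shell the
radial crossing length slightly exceeds the construction thickness away
from the axes (≈ +1.5% at the default eccentricity), an intrinsic property
of radial sampling, not a bug.

# QCT stage

The vBMD ROI is an ellipse on the mid-vertebral slice, centered at the
trabecular centroid, aspect-matched to the trabecular cross-section, scaled
to 100 mm² and shrunk in 3% steps until it lies entirely inside the
trabecular mask; placement fails (flagged) if no ellipse of ≥ 90 mm² fits.
The protocol's area window is 90–110 mm². A single mid-slice axial ROI is
used; a multi-slice or oblique-plane ROI is not specified anywhere and is
not implemented. vBMD = slope · mean(HU in ROI) + intercept; the default
calibration is the identity (slope 1, intercept 0) because the vendor
calibration is unavailable and every downstream grouping decision depends
only on the vBMD value. Classification: normal > 120, osteopenia 80–120
(both endpoints included), osteoporosis < 80 mg/cm³. Where a protocol
averages two vertebral levels, `final_vbmd()` averages what it is given;
single-phantom runs use one level.

# Cohort generator

The cohort generator reproduces the published summaries of the 169-subject
reference cohort: vBMD groups of 59/58/52 with per-group (mean, SD) for all
four parameters; sex totals 96 male / 73 female; age strata 71/55/43
overall, 29/23/21 female, 42/32/22 male. Parameters are drawn from group
Gaussians coupled by a Gaussian copula (default correlation 0.6 among
thickness/area/volume — structurally linked quantities — and 0.2 to
density); the marginal means/SDs, which are what the replay statistics and
acceptance targets consume, are unaffected by the coupling. Physically
positive parameters are floored at 0.01 of their unit when a draw is
negative (the printed volume SDs imply ~10% negative mass) and flagged
`truncated`, so tests can quantify the induced bias (≈ +0.008 mm on the
osteoporosis thickness mean, inside 3 SE at n = 10⁴).

Choices the published record does not determine, made once: the per-sex
normal/osteopenia split (only the osteoporosis counts per sex are
reported) is taken proportional — female 20/21, male 39/37; class is
coupled to age stratum at random; ages are uniform within stratum (70–87
in the open stratum, matching the reported maximum); within-class vBMD
distributions are truncated Gaussians (normal ~N(145, 20) above 120,
osteopenia ~N(100, 11) on [80, 120], osteoporosis ~N(62, 14) below 80).
Real cohorts are right-skewed in area and volume; the Gaussian working
model is deliberate (see statistics below).

The screening registry emits 326 records of which 157 carry exactly one of
five exclusion categories (32 fracture/tumor, 45 metabolic disease/drugs,
21 surgery, 38 image quality, 21 incomplete coverage), shuffled by seed.

# Statistics

All statistics are implemented from first principles (no external ROC or
ANOVA package) and cross-checked in the tests against independent oracles
(`stats::aov`, `pairwise.t.test`, trapezoidal ROC integration, bootstrap
variance).

- **ANOVA.** Classic one-way decomposition; the summary-statistic form
  computes F from (n, mean, SD) alone and is algebraically identical to the
  raw form (property-tested to 1e-10 relative). This is the replay route
  for published tables: with means/SDs rounded to two decimals, the six
  acceptance-anchored F values reproduce within 2%; a few other rows carry
  up to ~3% rounding error. LSD pairwise t tests (pooled variance, N−k df,
  unadjusted) run only when the omnibus p < 0.05, the conventional gate.
  Pairwise significance patterns are reported but not asserted against the
  published superscripts, whose legend is not available. Levene's test uses
  deviations from group *means* (the classic form, not Brown–Forsythe).
- **ROC.** AUC by the Mann–Whitney identity with ties counted ½ (identical
  to trapezoidal integration of the empirical ROC, property-tested to
  1e-12). Orientation "lower flags disease" is the default since every
  cortical parameter falls with osteoporosis. The operating point maximizes
  the Youden index over observed cutoff values with rule score ≤ cutoff;
  ties break toward higher sensitivity, then the lower cutoff, and are
  flagged — the reference software's exact tie rule is undocumented, so
  ties are surfaced rather than hidden. The 95% CI uses the DeLong variance
  with a normal approximation truncated to [0, 1]; published CIs may use a
  different engine and are checked qualitatively only.
- **DeLong test.** Placement-value (structural-component) covariance;
  Z = (AUC_a − AUC_b)/√var(diff), two-sided normal p; degenerate variance
  returns Z = 0, p = 1 by convention. Monte-Carlo type-I error at n = 200
  is verified to sit in [3%, 7%] at nominal 5%.
- **Binormal mixture AUC.** For Gaussian diseased vs Gaussian-mixture
  non-diseased groups, AUC = Σ wⱼ Φ((μⱼ−μ_d)/√(σⱼ²+σ_d²)), the closed-form
  bridge from printed summaries to an expected AUC. For thickness this
  gives 0.7485, matching the published empirical 0.75 — thickness is
  plausibly near-Gaussian. For area and volume the published AUCs (0.80)
  are *not* expected to reproduce under a Gaussian model fitted to the
  printed moments (real data are right-skewed; the Gaussian model yields
  ~0.77); these are checked for direction (AUC > 0.70) only. Published
  patient-data cutoffs (1.20 mm, 209.70 mm², 5.49 × 10³ mm³) and DeLong Z
  values depend on the unavailable raw cohort and are reproduced
  qualitatively, not numerically.

# Pipeline and determinism

Two execution modes. **Replay** (default): registry → exclusions →
synthetic cohort → summary-table ANOVA replays, cohort ANOVA/ROC/DeLong →
comparison report with deltas against the shipped reference values.
**Image**: phantoms → segmentation → morphometry → QCT, validated by
ground-truth recovery. Every stage derives its RNG stream from the master
seed; two runs with equal config are byte-identical at the JSON level, and
a config hash is recorded in each bundle. Volumes are rendered in the
10³ mm³ display convention; NIfTI-1 output stores HU as signed 16-bit with
unit scale slope, masks as unsigned 8-bit.

# Known limitations

- The segmentation surrogate is threshold-based and would not transfer to
  real anatomy with posterior elements or degenerative change.
- The phantom's shell is geometrically ideal; partial-volume bias at
  sub-voxel shell thickness (< 0.7 mm) is flagged but not corrected.
- Sex is a cohort covariate only; the imaging phantom is sex-agnostic.
- Per-sex ROC rows cannot be anchored to summaries (per-sex group moments
  are not published) and are exercised qualitatively.
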