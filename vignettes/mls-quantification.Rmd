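---
title: "Quantifying the muscle-lipid system of the thigh in 3D CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the muscle-lipid system of the thigh in 3D CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Muscle quality in ageing and in neuromuscular disease is expressed
radiologically as lipid infiltration of the thigh muscles: a diffuse
lowering of the muscle CT value ("washed-out" appearance, driven by
intramyocellular lipids) and speckled adipocyte clusters inside the
anatomical muscles ("moth-eaten" appearance, extramyocellular lipids,
EML).  Simple global HU thresholds cannot separate these compartments
because heavily infiltrated muscle, edema, dermis and genital organs all
share CT values, and because absolute HU varies across scanners.

`mlsct` implements an integrated, semi-automatic quantification of the
muscle-lipid system (MLS) of the thigh:

1. an anatomically scaled analysis slab (`VOI_US`) derived from femoral
   landmarks, so the measured region is reproducible across subjects and
   poses;
2. a hierarchical 3D segmentation of the deep fascia, the anatomical
   boundary between subcutaneous adipose tissue (SAT) and the
   intrafascial compartment (`VOI_IF`);
3. a subject-specific calibration that maps HU onto a contrast scale
   anchored at the subject's own adipose tissue (C = 0 at `CT_AT`) and at
   water measured in an in-scan phantom (C = 1 at `CT_H2O`);
4. a partition of `VOI_IF` into perimuscular adipose tissue (PAT),
   anatomical muscle (M), Gaussian-mixture-derived muscle tissue (MT),
   high-density muscle (HDM) and muscle-concentration bins;
5. density, volume and 3D texture features (granulometry average grain
   size, box-counting fractal dimension, sphericity) per compartment;
6. a validation harness for reanalysis precision (CV_RMS), cohort
   variation (CV_100), noise sensitivity and calibration sensitivity.

Because clinical cohorts cannot ship with a package, every stage is
exercised against a synthetic CT thigh phantom with exact ground truth.

## The segmentation model

**Analysis slab.**  Plane A passes through the femur's centre of mass at
the lesser-trochanter mid-height, perpendicular to the shaft axis (the
principal axis of the femur mask).  With P2 the femoral-head voxel
farthest from A on the head side and `d` the z-projection of that
distance, the slab holds `n = floor(0.5 d / s)` slices of thickness `s`,
starting at the distal end of the acetabulum and extending distally.
The head side is identified as the proximal (decreasing slice index)
direction; the trochanter slice and acetabulum slice are operator
inputs, since their automatic detection is a separate problem.

**Surface and calibration.**  The skin is found by thresholding at the
70% point of the HU spectrum inside a small sphere straddling the skin;
the body is the largest connected component above that threshold,
cavity-filled.  `CT_AT` is the mean of an adipose region grown from the
sphere inside [-190, -30] HU; `CT_H2O` comes from the water insert of an
in-scan calibration phantom (or a config value).  The per-voxel contrast
is `C = (HU - CT_AT) / (CT_H2O - CT_AT)`, unclamped, so dermis, bone and
vessels sit above 1.

**Grade-driven muscle classification.**  The operator grades the gross
muscle appearance G in {1, 2, 3} (3 = moth-eaten and washed out), which
sets `C_min = 0.75 - 0.15 G` and `alpha_min = 0.85 - 0.05 G`.  A voxel is
potential muscle iff it is at least 10 voxels deep under the skin, its
component connects to the femur, its contrast is at least `C_min`, and
the fraction of its 26 neighbours above `C_min` (the aggregation) is at
least `alpha_min`.  Ties pass everywhere (one global Heaviside
convention); neighbours outside the grid or body count as failing.  The
two largest components become the right/left leg; each is compacted by a
morphological closing with a z-elongated ellipsoid (default semi-axes
5, 5, 10 voxels -- the fascia is cylindrical and muscles run along the
leg) plus slice-wise contour filling, yielding `VOI_IFA` whose surface is
the fascia approximation FA.

**Fascia refinement.**  Candidate fascia voxels are grown from FA within
a 15-voxel Euclidean band: a voxel joins if it is not dermis-connected
(dermis = C > 1 voxels connected to the skin surface) and satisfies f:
accept outright when C > 1; for 0.5 <= C <= 1 accept iff
`HU >= mean26 - 2 SD26` of its neighbourhood (the local noise-adaptive
rule g); reject otherwise.  Gaps between FA and candidate conglomerates
are resolved by the ray-reflection model: from an operator seed the gap
is flood-filled, and every gap voxel casts rays along the 26 lattice
directions with unit voxel steps; a ray reflects if it reaches a
candidate or `VOI_IFA` voxel before travelling 15 voxels or leaving the
band, and a voxel is shielded at 17 of 26 reflections (65%).  Merged
with remaining slice-wise contour filling and smoothed by an opening
followed by a closing with a 2-voxel ball (which deletes porous
unselected clusters), the result is `VOI_IF`; its lateral surface is the
fascia.  The axial cut faces of the slab are not fascia, and the scan's
z-truncation faces are not skin -- both conventions matter on clipped
volumes, where muscle reaches the first and last slice.

**Compartments.**  `VOI_SAT` is the slab minus `VOI_IF` minus everything
dermis-connected.  Its 1-HU histogram, trimmed at both tails below 30%
of the modal count and symmetrized by mirroring the upper half about the
mode (SAT*), gives `T_AT = mean(SAT*) + 2 SD(SAT*)` -- robust against
vessels and edema in the SAT.  PAT is grown from fascia-adjacent
interior voxels strictly below `T_AT` (EML is, by definition, not
fascia-connected and stays inside M); `M = VOI_IF` minus PAT minus the
1-voxel-dilated femur.  A two-Gaussian decomposition of the `VOI_MLS`
(= SAT + IF) histogram, fitted by Levenberg-Marquardt least squares on
counts, yields the AT/MT intersection `a` and the muscle peak `b`; MT is
grown inside `VOI_IF` from voxels at or above `b`, accepting voxels
above `a`.  Muscle concentration is `100 (HU - T_AT)/(T_HDM - T_AT)`
with `T_HDM = 35 HU + CT_H2O` (the 35 HU constant derives from the
muscle of young athletes); integer-floored percentages fall into IMAT
(< 0), B2 (0-24), B3 (25-49), B4 (50-74), B5 (75-99) and B6 = HDM
(>= 100).  A percentage of exactly 0 is B2.

## Tunable parameters

All constants live in `load_config()` and can be overridden from
JSON/YAML or programmatically; out-of-range values are rejected with the
permissible range.

| key | default | unit | meaning |
|---|---|---|---|
| `surface_threshold_frac` | 0.70 | - | skin threshold within the sphere spectrum |
| `surface_sphere_radius` | 10 | voxels | placement sphere radius |
| `at_range` | [-190, -30] | HU | adipose growing window |
| `depth_min` | 10 | voxels | minimum depth under the skin |
| `candidate_band` | 15 | voxels | Euclidean reach of candidates and rays |
| `shielding_frac` | 0.65 | - | ray quorum (17 of 26) |
| `hist_cut_frac` | 0.30 | - | SAT-histogram tail cut |
| `hdm_constant` | 35 | HU | `T_HDM = constant + CT_H2O` |
| `tat_sd_factor`, `g_sd_factor` | 2 | - | SD multiples in `T_AT` and rule g |
| `closing_semiaxes` | (5, 5, 10) | voxels | compactification ellipsoid |
| `smoothing_radius` | 2 | voxels | final opening/closing ball |
| `femur_dilation` | 1 | voxels | cortical partial-volume guard |
| `gmm_*` | see docs | - | mixture fit bounds and initial widths |

## The synthetic phantom

`phantom_spec()` renders one or two elliptic-cylinder legs (2% smooth
per-slice radius jitter) built, outside in, of dermis shell, SAT, a thin
fascia sheet, an intrafascial space with a PAT rind over a 120 degree
sector, muscle with optional diffuse lipid infiltration and optional
AT-valued EML grains, and a femur; a water cylinder posterior to the
legs emulates the in-scan calibration phantom.  Defaults: 256x256x60
voxels at (1.2, 1.2, 1.0) mm, air -1000, SAT -100, muscle 40, dermis 60,
bone 700, water 0, edema/vessel 30 HU and Gaussian noise of SD 10 HU at
the reference exposure.

Two rendering choices deserve comment.  The fascia mean is 10 HU
(contrast about 1.1): the deep fascia is dense connective tissue whose
voxels image at muscle-like values -- which is exactly why the candidate
rule has its C > 1 branch -- while its *visibility* problem in real data
is thinness, reproduced here by the 1-voxel sheet.  Values in the
partial-volume range 0.5 <= C <= 1 still occur throughout noisy renders,
so both branches of f are exercised.  Second, the PAT rind covers only a
sector: candidates are *grown* from FA, so the fascia must keep direct
muscle contact somewhere, as it does anatomically; the rind sector is
where the seeds and the ray model do their work.

The phantom reproduces: tissue geometry and containment, tunable
washed-out and moth-eaten infiltration, operator inputs (grade, gap
seeds, acetabulum slice), calibration inputs, and exactly known noise.
It does not model beam hardening, scatter, reconstruction kernels,
partial-volume blur, or individually named muscles; passing tests
demonstrate algorithmic correctness under the stated tissue model, not
clinical accuracy on real anatomy.

## Numerical choices and degenerate inputs

* Ties pass at every threshold (one Heaviside convention); PAT keeps the
  strict `HU < T_AT` and MT growth the strict `HU > a`.  MT *seed*
  selection tolerates half a histogram bin below the fitted peak, since
  the 1-HU histogram cannot locate the peak more precisely and the
  fitted optimum carries optimizer-level error.
* A noiseless (or otherwise single-bin) SAT spectrum cannot support the
  trimmed statistic; `compute_t_at()` refuses it, and the pipeline falls
  back to the midpoint of `CT_AT` and `CT_H2O` with a raw-moment pseudo
  SAT* for mixture initialization.
* The mixture is fitted to raw counts with component heights >= 0 and
  widths >= 0.5 HU; the MT initial width is 15 HU.  The AT/MT
  intersection uses the closed-form quadratic root between the means
  (verified in tests against a 0.01-HU grid scan).
* Morphology is exact Euclidean (distance-transform based), so
  structuring elements honour anisotropic spacing; the candidate band
  distance is Euclidean.
* Box-counting uses dyadic scales up to one eighth of the largest extent
  of the counted set with origin-anchored boxes (coarser boxes saturate
  the count and bias the slope); an `eps` override exists for
  structured sets such as triadic constructions.
* The surface area behind sphericity uses projection-weighted face
  counting (each exposed face weighted by `|n|/||n||_1` of the local
  normal), exact for planar boundaries of any orientation and within
  about 1% on resolved spheres.
* Sessions carry all operator inputs *including the measured* `CT_H2O`;
  replaying a session on any volume therefore uses identical calibration
  numbers, which is what makes reanalysis precision exactly zero and
  noise experiments paired.

## Validation harness

`cv_rms()` implements the root-mean-square of per-subject coefficients
of variation (the standard reanalysis-precision statistic), and
`cv_100()` the cohort percentage CV divided by 100 -- implemented
literally (it equals SD/|mean|) so comparisons stay on the conventional
reporting scale.  `noise_experiment()` reruns the full pipeline on a
noise-augmented copy with the identical session and reports per-feature
percent changes rounded to one decimal; doubling the noise from SD sigma
requires adding `sqrt(3) sigma` (independent noise adds in quadrature),
and an exposure-based mode with SD proportional to `1/sqrt(mAs)` is also
provided.  `calibration_experiment()` shifts `CT_H2O` by +/- delta on a
fixed segmentation: every fixed-mask density then changes by exactly
`100 delta / |D|` percent -- the mechanism that makes low-density
compartments hyper-sensitive to water calibration -- while the
concentration bins are re-derived (T_HDM moves with the water value), so
the HDM density responds asymmetrically.

## Problem sizes used by the test-suite

The suite generates: a 160x160x36 one-leg phantom at (1.2, 1.2, 1.0) mm
for end-to-end runs; a 208x192x30 one-leg phantom at clinical in-plane
resolution (0.8 mm), noiseless, for compartment-volume recovery, where
the 1-voxel fascia sheet is a suitably small volume fraction; 256x256x60
two-leg phantoms for the noise-doubling nulls (three subjects in the
acceptance suite, since the reported noise-sensitivity figures are
cohort statistics); and million-draw mixtures for parameter recovery.

## Known limitations

* The optional deformable-model refinement of the fascia (useful for
  young, low-IMAT subjects) is not implemented; `VOI_IF` ends at the
  morphological smoothing stage.
* Automatic detection of the trochanter and acetabulum slices is out of
  scope; they are operator/session inputs.
* DICOM reading supports uncompressed explicit-VR little-endian series
  only; NIfTI and MetaImage are the native formats.
* IMAT-by-bins (concentration < 0%) and PAT + EML by connectivity are
  both reported and need not coincide; neither is forced onto the other.
* Box-counting FD of smooth *curved* digitized surfaces carries a known
  negative bias from the staircase shell at the finest scale; FD is
  meaningful here as a comparative texture index, as used in the
  reported feature roster.
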