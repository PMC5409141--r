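# mlsct — quantifying the muscle–lipid system of the thigh in 3D CT

`mlsct` is an R package for the semi-automatic segmentation and
quantification of the muscle–lipid system (MLS) of the thigh in
quantitative 3D CT, for researchers studying sarcopenia, myopathies and
osteoporosis who need reproducible muscle and adipose-tissue biomarkers
from standard-of-care hip/femur CT scans.

Lipid infiltration of muscle shows up in CT as a diffusely lowered
muscle density ("washed-out", intramyocellular lipids) and as adipocyte
clusters inside the anatomical muscles ("moth-eaten", extramyocellular
lipids, EML). Fixed HU thresholds cannot separate these compartments —
infiltrated muscle, edema and dermis overlap in HU, and absolute HU
drifts across scanners. The package instead:

- defines an anatomically scaled analysis slab VOI_US from femoral
  landmarks: n = ⌊0.5 d / s⌋ slices, with d the z-projected distance
  from the trochanter plane A to the femoral-head apex;
- segments the **deep fascia** hierarchically: a grade-dependent
  potential-muscle classification on the subject-specific contrast scale
  C (C = 0 at the adipose mean CT_AT, C = 1 at the water value CT_H2O),
  with C_min = 0.75 − 0.15·G and α_min = 0.85 − 0.05·G, morphological
  compactification (VOI_IFA), a local noise-adaptive candidate rule
  (accept at C > 1, or at 0.5 ≤ C ≤ 1 when HU ≥ mean₂₆ − 2·SD₂₆), and a
  26-direction **ray-reflection shielding** model (shielded at ≥ 17/26
  reflections) seeded by the operator in fascia–muscle gaps;
- partitions the intrafascial volume VOI_IF into SAT (outside), PAT,
  anatomical muscle M, Gaussian-mixture muscle tissue MT (two-Gaussian
  Levenberg–Marquardt fit of the tissue histogram; volume growing from
  the muscle peak b, accepting above the component intersection a),
  high-density muscle HDM and muscle-concentration bins anchored at
  T_AT = mean + 2 SD of the trimmed SAT spectrum and
  T_HDM = 35 HU + CT_H2O;
- computes densities D (mean HU − CT_H2O), GMM densities, relative
  volumes rV, granulometry average grain size G_avg, box-counting
  fractal dimension FD and sphericity Ψ per compartment;
- validates itself: reanalysis precision (CV_RMS), cohort variation
  (CV_100), noise-doubling and ±5 HU water-calibration sensitivity, all
  runnable on a **synthetic CT thigh phantom** with exact ground truth.

## Worked example

Generate the default two-leg phantom (256×256×60 voxels, SAT −100 HU,
muscle 40 HU, noise SD 10 HU), build a session from its ground-truth
operator inputs, and run the pipeline:

```r
library(mlsct)

ph <- generate_thigh_phantom(phantom_spec())
labs <- ph$truth$labels; dm <- dim(labs)

# operator inputs: one shielding seed in the perimuscular-fat gap every
# 10 slices, the true proximal slice, and the water value measured once
seeds <- NULL
for (k in seq(5, dm[3] - 4, by = 10)) {
  w <- which(labs[, , k] == 4)             # PAT label
  ij <- cbind((w - 1) %% dm[1], (w - 1) %/% dm[1])
  seeds <- rbind(seeds, c(ij[round(nrow(ij) / 2), ], k - 1))
}
session <- mls_session(grade = 2, seeds = seed_set(seeds, "gap", dm),
                       proximal_slice = ph$truth$acetabulum_slice,
                       n_slices = 50,
                       ct_h2o = ct_h2o_from_roi(ph$volume, truth_water_roi(ph)))

bundle <- run_segment(ph$volume, truth_mask(ph, "femur"), session)
bundle$ctx
#> <mls_calibration> CT_H2O = -0.08, CT_AT = -99.98, T_AT = -84.76, T_HDM = 34.92 HU
bundle$gmm_mls
#> <gmm_fit> AT: N(-100.0, 10.0^2) h=9185 | MT: N(39.7, 10.5^2) h=8582 | a=-31.72 b=39.67 (converged)
bundle$masks$VOI_IF
#> <voxel_mask> 'VOI_IF': 281731 of 256x256x60 voxels (7.16%)
```

The calibration recovered the phantom's true tissue values (water ≈ 0,
adipose ≈ −100 HU); the mixture fit found the adipose and muscle modes
within a fraction of an HU, and the fascia segmentation overlaps the
ground-truth intrafascial compartment with a Dice coefficient of 0.9999.
Density and volume features:

```r
run_features(bundle, ph$volume, features = c("D", "rV_IF", "rV_MLS"))
#>     voi feature      value units
#> 1   SAT       D  -99.90736    HU
#> 2    IF       D   83.08669    HU
#> 3     M       D   36.88239    HU
#> 4    MT       D   37.74230    HU
#> 5   HDM       D   45.12116    HU
#> 6  IMAT       D -101.27233    HU
#> 7     M   rV_IF    0.82526
#> 8    MT   rV_IF    0.81936
#> 9   HDM   rV_IF    0.52457
#> 10 IMAT   rV_IF    0.07262
#> 11  SAT  rV_MLS    0.42512
#> 12   IF  rV_MLS    0.57488
```

D(SAT) ≈ −100 HU is the water-calibrated subcutaneous fat density;
D(M) < 40 HU reflects the EML grains inside the anatomical muscle;
82% of the intrafascial volume is muscle, 7% intermuscular adipose
tissue by the concentration bins. `noise_experiment()` and
`calibration_experiment()` rerun this analysis under doubled noise or a
shifted water value, and `write_session()` persists the operator inputs
so any analysis replays bit-identically (CV_RMS = 0).

A thin command-line front end with subcommands `phantom`, `segment`,
`features`, `precision`, `noise` and `calib` is installed at
`inst/cli/mlsct`.

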