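---
title: "Methods: simulating and measuring radiomics-feature stability on accelerated diffusion MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring radiomics-feature stability on accelerated diffusion MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Radiomics studies on diffusion-derived parametric maps are only useful if the
features survive changes in acquisition. Simultaneous-multislice (SMS)
acceleration shortens multi-b-value DWI dramatically, but a higher
acceleration factor (AF) means a shorter repetition time (more T1 saturation)
and a higher noise level, both of which perturb the fitted maps and the
texture statistics computed on them. `radstab` provides a fully synthetic,
seeded test bed for this question: it simulates a two-group tumor cohort
imaged with three sequences (S1-S3 at AF 1-3), fits ADC, IVIM and DKI maps
voxelwise, extracts the standard 93-feature radiomics set per map for 2D
(largest axial slice) and 3D (full volume) segmentations, quantifies
per-feature stability across sequences, and screens the stable features for
association with the stage group.

## Signal models

Voxelwise signals follow, with `S0` the b = 0 intensity:

* IVIM (bi-exponential): `S(b) = S0 [ (1-f) e^(-bD) + f e^(-b(D+D*)) ]`,
  with tissue diffusivity `D` (mm^2/s), pseudodiffusion `D*`, and perfusion
  fraction `f`.
* DKI (kurtosis): `S(b) = S0 exp(-b MD + b^2 MD^2 MK / 6)` with mean
  diffusivity `MD` and mean kurtosis `MK`.
* `combined` (the cohort default): a perfusion compartment superimposed on
  the kurtosis decay, `S0 [ f e^(-b D*) + (1-f) e^(-b MD + b^2 MD^2 MK/6) ]`,
  so that both the IVIM fit over b <= 800 and the DKI fit over the 6-value
  kurtosis subset see realistic (slightly misspecified) data.
* ADC: the two-point decay between b = 0 and b = 800 s/mm^2.

The acquisition emulates an 11-b-value pelvic protocol
(0, 10, 20, 40, 80, 150, 200, 400, 800, 1500, 2000 s/mm^2 with
1,1,1,1,1,1,2,2,2,4,6 averages) on a 64 x 64 x 24 grid with 3.0 x 2.8 x 4.4 mm
voxels.

## What the generator emulates, and what it does not

Each subject is an ellipsoidal lesion (base radii 9 x 8 x 5 voxels, +-15%
per-subject jitter) in a uniform muscle-like background. Lesion parameters
are drawn per subject from physiological ranges (D 0.7-1.1, MD 1.0-1.5,
D* 8-16, all 10^-3 mm^2/s; f 0.06-0.14; MK 0.6-1.1; S0 350-450 a.u.).
Within-lesion heterogeneity is a zero-mean Gaussian-blob texture (40 blobs,
correlation length 3 voxels) applied multiplicatively and independently per
parameter map, normalized so the stated amplitude bounds the relative
deviation; the multiplicative form keeps every field positive and the
zero-mean normalization keeps the lesion mean at its drawn value.

Acceleration is emulated with exactly two knobs:

1. T1 saturation: all signals are scaled by `1 - exp(-TR/T1)` using the real
   repetition times of the three sequences (4700, 2500, 2000 ms).
2. Noise scale: Rician magnitude noise (magnitude of a complex Gaussian
   centred on the true signal) with per-channel sigma multiplied by 1.0, 1.1
   and 1.3 for AF 1, 2, 3; the per-b averages of the protocol are simulated
   as means of independent Rician draws, which preserves the low-SNR bias
   that destabilizes `D*` and `f`.

Not modelled: SMS reconstruction artifacts (slice leakage, residual
aliasing), motion, susceptibility, eddy currents, coil sensitivities, and
inter-reader segmentation differences beyond the seeded 1-voxel surface
perturbation used for the second-reader ICC. Passing tests therefore show
that the analysis machinery behaves correctly under noise- and
saturation-driven instability, not that real SMS images would yield the same
proportions.

## Calibrated defaults

The noise magnitude per AF is not something a desk study can take from
scanner tables, so the free defaults were calibrated once, before any
acceptance checks were written, to reproduce the qualitative image-quality
ordering S1 ~ S2 > S3 on the b = 800 volume (no significant S1-S2 difference
in the Friedman/Dunn comparison, S3 significantly worse), and then frozen:

* base Rician sigma 6 (b = 0 SNR about 60-75 for lesion S0 350-450);
* heterogeneity amplitude 0.25 (moderately heterogeneous tumors; this also
  sets the within-ROI "biological" SD that dominates the measured SNR);
* assumed effective T1 of 900 ms, at the short end of pelvic soft-tissue
  values, governing how much signal the short-TR sequences lose;
* quality ROIs measured in triplicate with 1-voxel jitter, emulating
  repeated manual outlining.

High-stage lesions get a 1.8x texture amplitude and 1.25x radii, so
gray-level-nonuniformity-type features (which scale with lesion size and
heterogeneity) separate the groups; setting both multipliers to 1 makes the
groups exchangeable, which the null-calibration tests exploit.

## Fitting

The IVIM fit is segmented: a log-linear fit over b >= 200 s/mm^2 (the
smallest b acquired with more than one average) gives `D` and, via the
intercept, `f`; `D*` follows from a golden-section search on the full
residual; by default all three parameters are then polished by bounded
Levenberg-Marquardt on the bi-exponential model with `S0` fixed at the
measured b = 0 signal. DKI is initialized by linear least squares on
`ln(S/S0)` and refined the same way. Bounds (D and MD in [1e-5, 4e-3],
D* in [1e-5, 0.5] mm^2/s with `D* >= D` enforced, f in [0, 1], MK in [0, 3])
keep low-SNR voxels physiological. Noiseless round trips recover IVIM
parameters to better than 1e-3 relative and DKI to 1e-6; a dense grid search
serves as the optimization oracle in the tests.

Goodness of fit is `R^2 = 1 - SS_res/SS_tot` per model. The exclusion rule
(`R^2 < 0.8`) is applied at subject level by default — a subject-sequence is
flagged when the ROI-median `R^2` of either model falls below threshold —
with a voxel-level variant available (`r2_level = "voxel"`), since published
descriptions of such rules rarely say which level is meant.

## Features

93 features per map: 18 first-order, 24 GLCM, 16 GLRLM, 16 GLSZM, 5 NGTDM,
14 GLDM — 558 per ROI mode over the six maps (ADC, D, D*, f, MD, MK).
Definitions follow the IBSI-consistent conventions of the mainstream
extraction tools; the complete id list is `feature_manifest()`. Choices the
underlying study left open, fixed here and configurable:

* discretization: fixed bin count, 32 bins per map (maps live on very
  different physical scales, so a common bin width would be meaningless);
* texture matrices at voxel distance 1; 4 unique in-plane directions in 2D,
  13 in 3D, features averaged unweighted over directions with at least one
  entry; zones and dependences use 8-/26-connectivity;
* GLDM dependence counts qualifying neighbors (alpha = 0); size-weighted
  GLDM features use j = dependence + 1 so an isolated voxel has size 1;
* degenerate statistics (single-voxel ROI, zero variance) return 0 with a
  flag rather than NaN; ratio guards use epsilon = 1e-6;
* no resampling: masks and maps share the simulation grid by construction.

Every texture family is verified against an independent brute-force
enumeration (explicit pair/run/zone/neighborhood loops) on seeded random
4 x 4 x 3 volumes, and direction-averaged 2D features are checked invariant
under in-plane 90-degree rotation.

## Stability statistics

For each (feature, map, ROI mode): Lin's concordance correlation coefficient
across subjects between S1-S2 and S1-S3 (population moments, the original
estimator), and the coefficient of variation across S1/S2/S3 computed within
subject (sample SD over absolute mean) and averaged over subjects with a
defined value. The "average of the combination" in the COV definition is
ambiguous in the source literature; computing it within subject measures
acquisition-induced variation rather than biological spread, which is the
quantity of interest here. Category boundaries are half-open — CCC: poor
(<= 0.5), moderate (0.5, 0.75], good (0.75, 0.9], excellent (> 0.9); COV:
excellent (< 0.05), good [0.05, 0.1], moderate (0.1, 0.2], poor (> 0.2) — so
the stable rule (CCC > 0.9 and COV <= 0.1) aligns exactly with the
good/excellent edges. A feature is stable when both CCC pairings exceed 0.9
and COV <= 0.1 (conservative reading; `stable_rule = "either"` relaxes it).

## Staging screen

Stable features from the analysis sequence (S2 by default, the quality/time
compromise) are tested low- vs high-stage with a Shapiro-Wilk-routed test
(Welch t when both groups look normal at alpha 0.05, otherwise Mann-Whitney
U, exact for small untied samples); survivors are gated on inter-reader
agreement ICC(2,1) (two-way random effects, absolute agreement, single
measure) computed against features re-extracted from a seeded 1-voxel
surface perturbation of the mask; features with ICC > 0.75 get a
pair-counting ROC AUC with high stage positive and no direction flipping.
No multiple-testing correction is applied, mirroring common practice in this
literature; the run report notes the caveat.

## Numerical and performance choices

All randomness flows through one master seed via a fixed integer-hash
derivation per (subject, stream), so every pipeline output is reproducible
bit for bit and cohort generation can stream subject by subject. Voxelwise
fits and texture-matrix accumulation are implemented in C++ (Rcpp); map
fitting is restricted to the lesion mask (all downstream statistics are
mask-local, so this is exact, not an approximation). The reference study
conditions — 40 subjects, three sequences, 64 x 64 x 24 grid — run in about
one minute per cohort; the qualitative-reproduction test repeats this over
10 master seeds. Tests that only need the quality metrics simulate the
b = 0/800 pair alone.

## Known limitations

* The AF emulation has exactly two knobs; acceleration effects beyond
  saturation and noise scaling are out of scope, so absolute stable-feature
  proportions should not be read as predictions for any scanner.
* The IVIM `D*` likelihood is nearly flat when `f` is small or `D*` large;
  the fit is accurate on clean signals but inherits large variance under
  noise — which is precisely the instability the pipeline is built to
  measure.
* The second reader is a mask perturbation, not an independent delineation;
  ICC values are best interpreted comparatively.
* COV is undefined for features with near-zero mean (e.g. skewness-like
  quantities); such values are flagged and excluded from averages rather
  than imputed.
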