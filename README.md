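# radstab

Stability of radiomics features on accelerated multi-b-value diffusion MRI —
a fully synthetic, seeded test bed.

## The problem

Quantitative maps fitted from multi-b-value diffusion-weighted MRI — the
apparent diffusion coefficient (ADC), the intravoxel-incoherent-motion (IVIM)
parameters D, D\* and f, and the diffusion-kurtosis (DKI) parameters MD and
MK — are increasingly mined for radiomics features. Simultaneous-multislice
(SMS) acceleration makes these long protocols clinically practical, but each
step in acceleration factor (AF) shortens the repetition time (more T1
saturation) and raises the noise level, and it is not obvious which features
survive. `radstab` is for methodologists who want to study that question
with known ground truth: it simulates a two-group tumor cohort imaged by
three sequences S1-S3 (AF 1-3), runs the complete analysis, and reports
which features remain stable and which of the stable ones separate the
groups.

The pipeline implements, end to end:

* forward signal models — IVIM
  `S(b) = S0[(1-f)e^(-bD) + f e^(-b(D+D*))]`, DKI
  `S(b) = S0 e^(-b·MD + b²·MD²·MK/6)`, and a combined perfusion+kurtosis
  model — over an 11-b-value scheme (0-2000 s/mm², protocol averages per b),
  with T1-saturation scaling `1 - e^(-TR/T1)` and averaged Rician noise per
  acceleration factor;
* voxelwise segmented+Levenberg-Marquardt IVIM fitting, log-linear+LM DKI
  fitting, two-point ADC, per-model R² with an `R² < 0.8` exclusion rule;
* the standard 93-feature radiomics set per map (18 first-order, 24 GLCM,
  16 GLRLM, 16 GLSZM, 5 NGTDM, 14 GLDM) for 2D (largest axial slice) and 3D
  (full volume) ROIs — 558 features per ROI mode over the six maps;
* stability statistics per feature: Lin's concordance correlation
  coefficient (CCC) between S1-S2 and S1-S3 across subjects, the
  within-subject coefficient of variation (COV) across S1-S3, four-tier
  categories, and the stable rule CCC > 0.9 with COV ≤ 0.1;
* image-quality comparison (SNR, CNR on the b = 800 volume) across
  sequences via Friedman + Dunn-Bonferroni;
* a staging screen of the stable features: Shapiro-routed Welch t /
  Mann-Whitney tests, an inter-reader ICC(2,1) gate against a perturbed-mask
  second reader, and ROC AUC.

## Worked example

A reduced cohort (4 low-stage, 8 high-stage subjects, 48×48×20 grid) runs in
a few seconds per subject:

```r
library(radstab)
cfg <- run_config(master_seed = 7, n_low = 4, n_high = 8,
                  grid_shape = c(48, 48, 20), lesion_radii = c(7, 6, 4),
                  write_images = FALSE)
res <- analyze_cohort(cfg)
```

which printed, for this seed:

```
stable 2D: 56/558 (10.0%)  stable 3D: 72/558 (12.9%)
mean CCC S1-S2 0.754, S1-S3 0.558
   roi_mode   map  n stable_proportion
2        3D   adc 93        0.19354839
4        3D     d 93        0.10752688
6        3D dstar 93        0.04301075
8        3D     f 93        0.07526882
10       3D    md 93        0.19354839
12       3D    mk 93        0.16129032
selected features: 67 of 128 stable; AUC 0.00-1.00
 map roi_mode                   feature_id      p_value       icc auc
 adc       2D  gldm_GrayLevelNonUniformity 0.0021044879 0.9797554   1
 adc       2D glrlm_GrayLevelNonUniformity 0.0018223185 0.9826272   1
 adc       2D glrlm_RunLengthNonUniformity 0.0012415437 0.9860628   1
 adc       3D          firstorder_Variance 0.0007900007 0.8440993   1
 adc       3D gldm_DependenceNonUniformity 0.0001862112 0.9623660   1
```

Reading this: agreement with the unaccelerated sequence drops from a mean
CCC of 0.75 (S1-S2) to 0.56 (S1-S3) — feature stability decreases with AF.
Only ~10-13% of features are stable under the default noise conditions, 3D
segmentation retains more stable features than 2D, the ADC map is the most
stable and the pseudodiffusion map (D\*) the least. Among stable features,
the staging screen keeps those with p < 0.05, inter-reader ICC > 0.75, and
reports the AUC for low- vs high-stage separation (an AUC of 0 is perfect
separation in the opposite direction; directions are never flipped). The
high-stage effect in the generator (larger, more heterogeneous lesions) is
deliberately strong, so nonuniformity-type features separate the groups
almost perfectly.

`run_pipeline(cfg, out_dir)` additionally persists every intermediate:
NIfTI series, masks and parametric maps, tidy CSV feature/stability/staging
tables, JSON reports and a Markdown summary. A thin command-line wrapper is
installed at `inst/scripts/radstab.R`
(`Rscript radstab.R run-all --config cfg.yaml --out DIR`).

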