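Package: radstab
Title: Stability of Radiomics Features on Accelerated Multi-b-Value Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for assessing how simultaneous
    multislice (SMS) acceleration and the choice of 2D versus 3D tumor
    segmentation affect the stability of radiomics features computed on
    diffusion parametric maps (ADC, IVIM D/D*/f, DKI MD/MK). Provides a
    synthetic multi-b-value DWI cohort generator with Rician noise and
    T1-saturation acceleration effects, voxelwise IVIM/DKI/ADC model fitting
    with goodness-of-fit exclusion, 93-feature radiomics extraction
    (first-order, GLCM, GLRLM, GLSZM, NGTDM, GLDM), concordance-correlation
    and coefficient-of-variation stability statistics with categorical
    summaries, image-quality comparison across acceleration factors, and a
    stage-association feature screen (normality-routed two-group tests,
    two-rater ICC, ROC/AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, RNifti, jsonlite, yaml, stats, utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
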