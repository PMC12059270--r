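#' Pipeline run configuration
#'
#' Collects every knob of the simulate -> fit -> extract -> stability ->
#' staging pipeline in one validated list. Defaults reproduce the package's
#' reference study conditions: a 40-subject cohort (12 low / 28 high stage),
#' the 11-b-value scheme, AF profiles S1-S3 with noise scales 1.0/1.1/1.3,
#' and sequence S2 for the staging analysis.
#'
#' @param master_seed integer master seed
#' @param n_low,n_high cohort group sizes
#' @param sigma Rician noise scale at AF = 1
#' @param t1_ms assumed tissue T1 for saturation scaling
#' @param sigma_scales AF noise-scale multipliers (S1, S2, S3)
#' @param grid_shape phantom grid
#' @param lesion_radii base lesion ellipsoid radii in voxels
#' @param heterogeneity_amplitude within-lesion texture amplitude (fraction
#'   of the parameter value) for low-stage lesions
#' @param n_bins gray levels for feature discretization
#' @param analysis_sequence sequence used for the staging screen
#' @param stable_rule "both" or "either" (see [stability_table()])
#' @param stage_amplitude,stage_radius high-stage effect multipliers
#' @param refine_full_nlls,r2_threshold,r2_level see [fit_options()]
#' @param write_images persist NIfTI intermediates in [run_pipeline()]
#' @return a `run_config` list
#' @export
run_config <- function(master_seed = 1L, n_low = 12L, n_high = 28L,
                       sigma = 6, t1_ms = 900,
                       sigma_scales = c(1, 1.1, 1.3),
                       grid_shape = c(64, 64, 24),
                       lesion_radii = c(9, 8, 5),
                       heterogeneity_amplitude = 0.25, n_bins = 32,
                       analysis_sequence = "S2",
                       stable_rule = "both",
                       stage_amplitude = 1.8, stage_radius = 1.25,
                       refine_full_nlls = TRUE, r2_threshold = 0.8,
                       r2_level = "subject", write_images = TRUE) {
  assert_that(analysis_sequence %in% c("S1", "S2", "S3"),
              "analysis_sequence must be S1, S2 or S3")
  structure(list(master_seed = as.integer(master_seed),
                 n_low = as.integer(n_low), n_high = as.integer(n_high),
                 sigma = sigma, t1_ms = t1_ms, sigma_scales = sigma_scales,
                 grid_shape = as.integer(grid_shape),
                 lesion_radii = lesion_radii,
                 heterogeneity_amplitude = heterogeneity_amplitude,
                 n_bins = n_bins,
                 analysis_sequence = analysis_sequence,
                 stable_rule = stable_rule,
                 stage_amplitude = stage_amplitude,
                 stage_radius = stage_radius,
                 refine_full_nlls = refine_full_nlls,
                 r2_threshold = r2_threshold, r2_level = r2_level,
                 write_images = write_images),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [run_config()] arguments
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Simulate and analyze a full cohort in memory
#'
#' Streams the cohort subject by subject: phantom generation, forward signal
#' simulation, AF emulation, Rician noise, parametric-map fitting over the
#' lesion, 93-feature extraction per map and ROI mode, image-quality
#' measurement on the b = 800 volume, then the stability table and (when
#' requested) the stage-association screen with a perturbed-mask second
#' reader on the analysis sequence.
#'
#' @param config a [run_config()]
#' @param do_staging run the ICC/ROC staging screen (needs the second-rater
#'   extraction; skip for stability-only studies)
#' @param artifact_dir optional directory: when given, per-subject NIfTI
#'   intermediates are written there as the cohort streams through
#' @param verbose print per-subject progress
#' @return list with `labels`, `quality`, `quality_stats`, `features`,
#'   `rater_b`, `stability`, `summary`, `staging`, `exclusions`
#' @export
analyze_cohort <- function(config = run_config(), do_staging = TRUE,
                           artifact_dir = NULL, verbose = FALSE) {
  base_spec <- cohort_base_spec(
    grid_shape = config$grid_shape, lesion_radii = config$lesion_radii,
    heterogeneity = list(amplitude = config$heterogeneity_amplitude))
  af_profiles <- default_af_profiles(t1_ms = config$t1_ms,
                                     sigma_scales = config$sigma_scales)
  options <- fit_options(refine_full_nlls = config$refine_full_nlls,
                         r2_threshold = config$r2_threshold,
                         r2_level = config$r2_level)
  disc <- discretization_config(n_bins = config$n_bins)
  scheme <- default_bvalue_scheme()
  stage_effect <- list(amplitude = config$stage_amplitude,
                       radius = config$stage_radius)
  seed <- config$master_seed
  n <- config$n_low + config$n_high
  stages <- rep(c("low", "high"), c(config$n_low, config$n_high))
  b800 <- which(scheme$b == 800)

  feat_rows <- list()
  rater_b_rows <- list()
  qual_rows <- list()
  excl_rows <- list()
  labels <- data.frame(subject_id = sprintf("sub%03d", seq_len(n)),
                       stage = stages, stringsAsFactors = FALSE)

  for (i in seq_len(n)) {
    sub <- cohort_subject(seed, i, stages[i], base_spec, af_profiles,
                          config$sigma, scheme, stage_effect,
                          radius_jitter = 0.15)
    mask <- sub$truth$lesion_mask
    ref <- reference_roi_mask(sub$truth)
    roi2d <- select_2d_slice(mask)
    ref_slice <- array(FALSE, dim = dim(ref))
    ref_slice[, , roi2d$slice_index] <- ref[, , roi2d$slice_index]
    if (!any(ref_slice)) ref_slice <- ref
    mask_b <- NULL
    if (do_staging) {
      mask_b <- perturb_mask(mask, seed = derive_seed(seed, i, 99L))
    }
    if (!is.null(artifact_dir)) {
      sdir <- file.path(artifact_dir, sub$subject_id)
      dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      write_mask(mask, nifti_path(sdir, "lesion_mask"),
                 sub$truth$spec$voxel_spacing)
    }
    for (s in names(sub$series)) {
      ser <- sub$series[[s]]
      vol800 <- ser$volumes[, , , b800]
      # triplicate measurement with 1-voxel jitter emulates repeated manual
      # outlining of the quality ROIs
      tum <- measure_roi_stats(vol800, roi2d$mask, jitter = 1,
                               seed = derive_seed(seed, i, 50L),
                               label = "tumor")
      mus <- measure_roi_stats(vol800, ref_slice, jitter = 1,
                               seed = derive_seed(seed, i, 51L),
                               label = "muscle")
      qual_rows[[paste(i, s)]] <- data.frame(
        subject_id = sub$subject_id, sequence = s,
        snr = snr(tum), cnr = cnr(tum, mus), stringsAsFactors = FALSE)

      fit_region <- if (do_staging && s == config$analysis_sequence) {
        mask | mask_b
      } else mask
      ms <- fit_map_set(ser, options, mask = fit_region)
      excl_rows[[paste(i, s)]] <- data.frame(
        subject_id = sub$subject_id, sequence = s,
        median_r2_ivim = unname(ms$median_r2["ivim"]),
        median_r2_dki = unname(ms$median_r2["dki"]),
        excluded = ms$excluded, stringsAsFactors = FALSE)

      fe <- extract_features(ms, mask, config = disc)
      fe$subject_id <- sub$subject_id
      fe$sequence <- s
      feat_rows[[paste(i, s)]] <- fe

      if (do_staging && s == config$analysis_sequence) {
        fb <- extract_features(ms, mask_b, config = disc)
        fb$subject_id <- sub$subject_id
        fb$sequence <- s
        rater_b_rows[[i]] <- fb
      }
      if (!is.null(artifact_dir)) {
        sdir <- file.path(artifact_dir, sub$subject_id)
        write_dwi_series(ser, sdir)
        write_map_set(ms, sdir, stem = paste0("maps_", s))
      }
    }
    if (verbose) message("subject ", i, "/", n, " done")
  }

  features <- do.call(rbind, feat_rows)
  rownames(features) <- NULL
  quality <- do.call(rbind, qual_rows)
  rownames(quality) <- NULL
  exclusions <- do.call(rbind, excl_rows)
  rownames(exclusions) <- NULL

  quality_stats <- list(
    snr = compare_quality(data.frame(subject_id = quality$subject_id,
                                     sequence = quality$sequence,
                                     value = quality$snr)),
    cnr = compare_quality(data.frame(subject_id = quality$subject_id,
                                     sequence = quality$sequence,
                                     value = quality$cnr)))

  stability <- stability_table(features, stable_rule = config$stable_rule)
  summary <- summarize_stability(stability)

  staging <- NULL
  rater_b <- NULL
  if (do_staging) {
    rater_b <- do.call(rbind, rater_b_rows)
    rownames(rater_b) <- NULL
    fa <- features[features$sequence == config$analysis_sequence, ]
    staging <- staging_screen(fa, stability, rater_b, labels)
  }

  list(config = config, labels = labels, quality = quality,
       quality_stats = quality_stats, features = features,
       rater_b = rater_b, stability = stability, summary = summary,
       staging = staging, exclusions = exclusions)
}

#' Run the full pipeline and persist all artifacts
#'
#' Executes [analyze_cohort()] and writes every table (CSV), the run reports
#' (JSON), the configuration, and a Markdown summary to `out_dir`; with
#' `config$write_images` the per-subject NIfTI intermediates (series, lesion
#' masks, parametric maps) are persisted as well.
#'
#' @param config a [run_config()]
#' @param out_dir output directory
#' @param verbose print progress
#' @return the [analyze_cohort()] result, invisibly
#' @export
run_pipeline <- function(config = run_config(), out_dir, verbose = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- analyze_cohort(config, do_staging = TRUE,
                        artifact_dir = if (config$write_images)
                          file.path(out_dir, "images") else NULL,
                        verbose = verbose)
  write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  write.csv(res$labels, file.path(out_dir, "cohort_metadata.csv"),
            row.names = FALSE)
  write.csv(res$quality, file.path(out_dir, "image_quality.csv"),
            row.names = FALSE)
  write.csv(res$features, file.path(out_dir, "features.csv"),
            row.names = FALSE)
  write.csv(res$rater_b, file.path(out_dir, "features_rater_b.csv"),
            row.names = FALSE)
  write.csv(res$stability, file.path(out_dir, "stability_records.csv"),
            row.names = FALSE)
  write.csv(res$summary$stable_by_map,
            file.path(out_dir, "stable_proportions.csv"), row.names = FALSE)
  write.csv(res$summary$category_overall,
            file.path(out_dir, "category_proportions.csv"), row.names = FALSE)
  write.csv(res$staging, file.path(out_dir, "staging_records.csv"),
            row.names = FALSE)
  write.csv(res$exclusions, file.path(out_dir, "fit_exclusions.csv"),
            row.names = FALSE)
  write_json(list(quality = res$quality_stats,
                  median_ccc_s1s2 = median(res$stability$ccc_s1s2,
                                           na.rm = TRUE),
                  median_ccc_s1s3 = median(res$stability$ccc_s1s3,
                                           na.rm = TRUE)),
             file.path(out_dir, "run_report.json"), auto_unbox = TRUE,
             digits = NA)
  writeLines(pipeline_summary_md(res), file.path(out_dir, "summary.md"))
  invisible(res)
}

pipeline_summary_md <- function(res) {
  so <- res$summary$stable_overall
  sm <- res$summary$stable_by_map
  qp <- function(m) {
    q <- res$quality_stats[[m]]
    sprintf("%s: Friedman p = %.3g; S1-S2 p = %.3g, S2-S3 p = %.3g, S1-S3 p = %.3g",
            toupper(m), q$friedman_p, q$pairwise$p_adj[1],
            q$pairwise$p_adj[2], q$pairwise$p_adj[3])
  }
  c("# Cohort analysis summary", "",
    sprintf("Subjects: %d low / %d high stage; analysis sequence %s.",
            sum(res$labels$stage == "low"), sum(res$labels$stage == "high"),
            res$config$analysis_sequence),
    "", "## Image quality (b = 800)", qp("snr"), qp("cnr"), "",
    "## Stability",
    sprintf("Mean CCC S1-S2 = %.3f, S1-S3 = %.3f.",
            mean(res$stability$ccc_s1s2, na.rm = TRUE),
            mean(res$stability$ccc_s1s3, na.rm = TRUE)),
    vapply(seq_len(nrow(so)), function(r) {
      sprintf("Stable proportion (%s): %.1f%% of %d features.",
              so$roi_mode[r], 100 * so$stable_proportion[r], so$n[r])
    }, ""),
    "", "Per map:",
    vapply(seq_len(nrow(sm)), function(r) {
      sprintf("- %s %s: %.1f%%", sm$map[r], sm$roi_mode[r],
              100 * sm$stable_proportion[r])
    }, ""),
    "", "## Staging screen",
    if (is.null(res$staging) || nrow(res$staging) == 0) {
      "No stable features entered the screen."
    } else {
      sprintf("%d of %d stable features selected (p < 0.05, ICC > 0.75); AUC range %s.",
              sum(res$staging$selected, na.rm = TRUE), nrow(res$staging),
              if (any(!is.na(res$staging$auc)))
                sprintf("%.2f-%.2f", min(res$staging$auc, na.rm = TRUE),
                        max(res$staging$auc, na.rm = TRUE)) else "-")
    })
}
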