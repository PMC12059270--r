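# NIfTI-1 + sidecar I/O. Volumes are written as float64 so round trips are
# lossless; the b-value table travels as TSV and metadata as JSON.

nifti_path <- function(dir, stem) file.path(dir, paste0(stem, ".nii.gz"))

write_volume <- function(arr, path, spacing) {
  attr(arr, "pixdim") <- spacing[seq_len(min(3, length(dim(arr))))]
  img <- RNifti::asNifti(arr, datatype = "double")
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  attr(arr, "spacing") <- RNifti::pixdim(img)[1:3]
  arr
}

#' Write a DWI series as NIfTI + b-table TSV + metadata JSON
#'
#' @param series a [dwi_series()]
#' @param dir output directory (created if needed)
#' @param stem file-name stem; writes `<stem>.nii.gz`, `<stem>_bvals.tsv`,
#'   `<stem>_meta.json`
#' @return the stem, invisibly
#' @export
write_dwi_series <- function(series, dir, stem = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- stem %||% paste0(series$subject_id, "_", series$sequence_label)
  write_volume(series$volumes, nifti_path(dir, stem), series$spacing)
  write.table(series$scheme, file.path(dir, paste0(stem, "_bvals.tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(subject_id = series$subject_id,
               sequence_label = series$sequence_label,
               spacing = series$spacing,
               af_profile = if (is.null(series$af_profile)) NULL else
                 unclass(series$af_profile))
  write_json(meta, file.path(dir, paste0(stem, "_meta.json")),
             auto_unbox = TRUE, digits = NA, null = "null")
  invisible(stem)
}

#' Read a DWI series written by [write_dwi_series()]
#'
#' @param dir directory
#' @param stem file-name stem
#' @return a [dwi_series()]
#' @export
read_dwi_series <- function(dir, stem) {
  vols <- read_volume(nifti_path(dir, stem))
  attr(vols, "spacing") <- NULL
  bt <- read.delim(file.path(dir, paste0(stem, "_bvals.tsv")))
  meta <- read_json(file.path(dir, paste0(stem, "_meta.json")),
                    simplifyVector = TRUE)
  prof <- NULL
  if (!is.null(meta$af_profile) && length(meta$af_profile) > 0) {
    prof <- af_profile(meta$af_profile$af, meta$af_profile$tr_ms,
                       meta$af_profile$t1_ms, meta$af_profile$sigma_scale)
  }
  dwi_series(vols, bvalue_scheme(bt$b, bt$n_averages),
             sequence_label = meta$sequence_label, af_profile = prof,
             subject_id = meta$subject_id, spacing = as.numeric(meta$spacing))
}

#' Write a binary mask as NIfTI-1
#'
#' @param mask logical 3D array
#' @param path output path (.nii.gz)
#' @param spacing voxel spacing in mm
#' @export
write_mask <- function(mask, path, spacing = c(1, 1, 1)) {
  write_volume(array(as.numeric(mask), dim = dim(mask)), path, spacing)
  invisible(path)
}

#' Read a binary mask written by [write_mask()]
#'
#' @param path NIfTI path
#' @return logical 3D array
#' @export
read_mask <- function(path) {
  arr <- read_volume(path)
  sp <- attr(arr, "spacing")
  out <- arr > 0.5
  attr(out, "spacing") <- sp
  out
}

#' Write a parametric map set (six maps + R^2 maps + fit report)
#'
#' @param map_set a `parametric_map_set`
#' @param dir output directory
#' @param stem file-name stem prefix
#' @return the stem, invisibly
#' @export
write_map_set <- function(map_set, dir, stem = "maps") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in names(map_set$maps)) {
    write_volume(map_set$maps[[m]], nifti_path(dir, paste0(stem, "_", m)),
                 map_set$spacing)
  }
  for (m in names(map_set$r2)) {
    write_volume(map_set$r2[[m]], nifti_path(dir, paste0(stem, "_r2_", m)),
                 map_set$spacing)
  }
  write_mask(map_set$fit_mask, nifti_path(dir, paste0(stem, "_fitmask")),
             map_set$spacing)
  report <- list(median_r2 = as.list(map_set$median_r2),
                 excluded = map_set$excluded,
                 spacing = map_set$spacing,
                 options = unclass(map_set$options))
  write_json(report, file.path(dir, paste0(stem, "_fit_report.json")),
             auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' Read a parametric map set written by [write_map_set()]
#'
#' R^2 and valid-mask detail beyond the fitted mask is restored from the
#' written volumes; options come from the JSON report.
#'
#' @param dir directory
#' @param stem file-name stem prefix
#' @return a `parametric_map_set`
#' @export
read_map_set <- function(dir, stem = "maps") {
  report <- read_json(file.path(dir, paste0(stem, "_fit_report.json")),
                      simplifyVector = TRUE)
  maps <- lapply(setNames(MAP_NAMES, MAP_NAMES), function(m)
    read_volume(nifti_path(dir, paste0(stem, "_", m))))
  r2 <- lapply(setNames(c("ivim", "dki"), c("ivim", "dki")), function(m)
    read_volume(nifti_path(dir, paste0(stem, "_r2_", m))))
  fit_mask <- read_mask(nifti_path(dir, paste0(stem, "_fitmask")))
  valid <- list(adc = !is.na(maps$adc), ivim = !is.na(maps$d),
                dki = !is.na(maps$md))
  opts <- fit_options(ivim_split_b = report$options$ivim_split_b,
                      bounds = report$options$bounds,
                      refine_full_nlls = report$options$refine_full_nlls,
                      r2_threshold = report$options$r2_threshold,
                      r2_level = report$options$r2_level)
  structure(list(maps = lapply(maps, function(a) { attr(a, "spacing") <- NULL; a }),
                 r2 = lapply(r2, function(a) { attr(a, "spacing") <- NULL; a }),
                 valid = valid, fit_mask = fit_mask,
                 median_r2 = unlist(report$median_r2),
                 excluded = report$excluded,
                 spacing = as.numeric(report$spacing), options = opts),
            class = "parametric_map_set")
}
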