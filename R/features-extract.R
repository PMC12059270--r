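MAP_NAMES <- c("adc", "d", "dstar", "f", "md", "mk")
FAMILY_SIZES <- c(firstorder = 18L, glcm = 24L, glrlm = 16L, glszm = 16L,
                  ngtdm = 5L, gldm = 14L)

#' All 93 feature identifiers
#'
#' Feature ids are "family_Name" strings: 18 first-order, 24 GLCM, 16 GLRLM,
#' 16 GLSZM, 5 NGTDM and 14 GLDM features.
#'
#' @return a data frame with columns `feature_id`, `family`, `name`
#' @export
feature_manifest <- function() {
  fam <- list(firstorder = FIRSTORDER_NAMES, glcm = GLCM_NAMES,
              glrlm = GLRLM_NAMES, glszm = GLSZM_NAMES,
              ngtdm = NGTDM_NAMES, gldm = GLDM_NAMES)
  do.call(rbind, lapply(names(fam), function(f) {
    data.frame(feature_id = paste0(f, "_", fam[[f]]), family = f,
               name = fam[[f]], stringsAsFactors = FALSE)
  }))
}

#' Extract the 93-feature vector from one map and ROI
#'
#' Discretizes the masked intensities and runs all six feature families.
#' For `mode = "2D"` the mask must lie on a single axial slice (see
#' [select_2d_slice()]); texture matrices then use the 4 in-plane
#' directions, otherwise the 13 unique 3D directions.
#'
#' @param values 3D numeric array (a parametric map)
#' @param mask logical 3D array selecting the ROI
#' @param mode "2D" or "3D"
#' @param spacing voxel spacing in mm
#' @param config a [discretization_config()]
#' @return data frame with columns `feature_id`, `value`, `degenerate`
#' @export
compute_features <- function(values, mask, mode = c("3D", "2D"),
                             spacing = c(1, 1, 1),
                             config = discretization_config()) {
  mode <- match.arg(mode)
  assert_that(any(mask), "mask is empty")
  v <- values[mask]
  assert_that(all(is.finite(v)), "masked values must be finite")
  lev_vals <- discretize(v, config)
  ng <- attr(lev_vals, "ng")
  lev <- array(0L, dim = dim(mask))
  lev[mask] <- lev_vals

  if (mode == "2D") {
    k <- unique(which(mask, arr.ind = TRUE)[, 3])
    assert_that(length(k) == 1L, "2D mode requires a single-slice mask")
    lev <- lev[, , k, drop = FALSE]
  }
  fo <- first_order_features(v, lev_vals, spacing = spacing, config = config)
  fams <- list(
    firstorder = fo,
    glcm = glcm_features(lev, ng = ng, mode = mode),
    glrlm = glrlm_features(lev, ng = ng, mode = mode),
    glszm = glszm_features(lev, ng = ng, mode = mode),
    ngtdm = ngtdm_features(lev, ng = ng, mode = mode),
    gldm = gldm_features(lev, ng = ng, mode = mode)
  )
  do.call(rbind, lapply(names(fams), function(f) {
    x <- fams[[f]]
    data.frame(feature_id = paste0(f, "_", names(x)),
               value = unname(x),
               degenerate = unname(attr(x, "degenerate")),
               stringsAsFactors = FALSE)
  }))
}

#' Extract features from all six parametric maps
#'
#' For every map the ROI is intersected with the map's valid-fit mask, then
#' the 93 features are computed per requested ROI mode (558 per mode over the
#' six maps). The 2D slice is the largest-area axial slice of the input ROI.
#' Maps with an empty valid intersection yield NA values with a missing flag.
#'
#' @param map_set a `parametric_map_set` from [fit_map_set()]
#' @param mask logical 3D array (the tumor ROI)
#' @param config a [discretization_config()]
#' @param modes character vector among "2D", "3D"
#' @return data frame with columns `map`, `roi_mode`, `feature_id`, `value`,
#'   `degenerate`
#' @export
extract_features <- function(map_set, mask, config = discretization_config(),
                             modes = c("2D", "3D")) {
  assert_that(inherits(map_set, "parametric_map_set"),
              "map_set must come from fit_map_set()")
  assert_that(any(mask), "mask is empty")
  manifest <- feature_manifest()
  out <- list()
  for (mode in modes) {
    roi <- if (mode == "2D") select_2d_slice(mask)$mask else mask
    for (m in MAP_NAMES) {
      valid <- roi & map_set$valid[[MAP_MODEL[[m]]]]
      if (!any(valid)) {
        df <- data.frame(feature_id = manifest$feature_id, value = NA_real_,
                         degenerate = TRUE, stringsAsFactors = FALSE)
      } else {
        df <- compute_features(map_set$maps[[m]], valid, mode = mode,
                               spacing = map_set$spacing, config = config)
      }
      df$map <- m
      df$roi_mode <- mode
      out[[paste(mode, m)]] <- df
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("map", "roi_mode", "feature_id", "value", "degenerate")]
}
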