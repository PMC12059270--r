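#' Select the largest-area axial slice of a 3D ROI
#'
#' Returns the 2D ROI used by the single-slice feature mode: all mask voxels
#' on the axial (third-axis) slice with the maximal in-slice ROI area, ties
#' broken by the lowest slice index.
#'
#' @param mask_3d logical 3D array, non-empty
#' @return a `roi_mask` list: `mask` (3D array restricted to the slice),
#'   `mode = "2D"`, `slice_index`
#' @export
select_2d_slice <- function(mask_3d) {
  assert_that(any(mask_3d), "mask is empty")
  areas <- apply(mask_3d, 3, sum)
  k <- which.max(areas)  # which.max takes the first maximum: lowest slice
  out <- array(FALSE, dim = dim(mask_3d))
  out[, , k] <- mask_3d[, , k]
  structure(list(mask = out, mode = "2D", slice_index = as.integer(k)),
            class = "roi_mask")
}

#' Gray-level discretization settings
#'
#' @param method "fixed_bin_count" (uniform bins over the masked intensity
#'   range; the default, 32 bins) or "fixed_bin_width"
#' @param n_bins number of gray levels for fixed_bin_count (>= 2)
#' @param bin_width bin width in map units for fixed_bin_width (> 0)
#' @return a `discretization_config` list
#' @export
discretization_config <- function(method = c("fixed_bin_count",
                                             "fixed_bin_width"),
                                  n_bins = 32, bin_width = NULL) {
  method <- match.arg(method)
  if (method == "fixed_bin_count") {
    assert_that(is_scalar_number(n_bins) && n_bins >= 2, "n_bins must be >= 2")
  } else {
    assert_that(is_scalar_number(bin_width) && bin_width > 0,
                "bin_width must be > 0")
  }
  structure(list(method = method, n_bins = n_bins, bin_width = bin_width),
            class = "discretization_config")
}

#' Discretize masked intensities to integer gray levels
#'
#' Fixed bin count maps the masked intensity range uniformly onto 1..Ng with
#' the maximum value assigned to Ng; a constant region collapses to a single
#' level. Fixed bin width assigns level floor(x/w) - floor(min/w) + 1.
#' Levels are invariant to affine intensity rescaling (with positive slope)
#' under fixed bin count.
#'
#' @param values numeric vector of masked, finite intensities
#' @param config a [discretization_config()]
#' @return integer vector of gray levels in 1..Ng with attribute `ng`
#' @export
discretize <- function(values, config = discretization_config()) {
  assert_that(length(values) >= 1, "at least one voxel is required")
  assert_that(all(is.finite(values)), "values must be finite")
  if (config$method == "fixed_bin_count") {
    lo <- min(values); hi <- max(values)
    if (hi == lo) {
      lev <- rep(1L, length(values))
      attr(lev, "ng") <- 1L
      return(lev)
    }
    n <- as.integer(config$n_bins)
    lev <- pmin(as.integer(floor((values - lo) / (hi - lo) * n)) + 1L, n)
    attr(lev, "ng") <- n
  } else {
    w <- config$bin_width
    lev <- as.integer(floor(values / w) - floor(min(values) / w)) + 1L
    attr(lev, "ng") <- max(lev)
  }
  lev
}
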