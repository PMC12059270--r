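PARAM_NAMES <- c("s0", "d", "dstar", "f", "md", "mk")

#' Specification of a synthetic diffusion phantom
#'
#' Defines the grid, an ellipsoidal lesion, per-tissue diffusion parameters
#' and a within-lesion heterogeneity texture. Parameter entries may be single
#' values or length-2 ranges (sampled uniformly when the phantom is built).
#' Units: diffusivities (`d`, `dstar`, `md`) in mm^2/s, `f` a fraction in
#' [0, 1], `mk` unitless, `s0` arbitrary signal units.
#'
#' @param grid_shape voxel counts (x, y, z)
#' @param voxel_spacing mm per axis
#' @param lesion_center lesion centre in voxel coordinates (default: grid centre)
#' @param lesion_radii ellipsoid radii in voxels (all >= 2)
#' @param background_params named list of tissue parameters outside the lesion
#' @param lesion_params named list of tissue parameters (or ranges) inside
#' @param heterogeneity list with `n_blobs`, `amplitude` (fraction of the
#'   parameter value), `corr_length` (voxels): a smoothed Gaussian-blob
#'   multiplicative texture applied within the lesion
#' @param stage_label "low" or "high"; high-stage lesions get their texture
#'   amplitude multiplied by `stage_amp_multiplier`
#' @param stage_amp_multiplier heterogeneity multiplier for high stage
#' @param signal_model "ivim", "dki" or "combined"
#' @param seed RNG seed making the phantom deterministic
#' @return a `phantom_spec` list
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 24),
                         voxel_spacing = c(3.0, 2.8, 4.4),
                         lesion_center = NULL,
                         lesion_radii = c(9, 8, 5),
                         background_params = list(s0 = 320, d = 1.4e-3,
                                                  dstar = 8e-3, f = 0.05,
                                                  md = 1.5e-3, mk = 0.6),
                         lesion_params = list(s0 = 400, d = 0.9e-3,
                                              dstar = 12e-3, f = 0.10,
                                              md = 1.2e-3, mk = 0.85),
                         heterogeneity = list(n_blobs = 40, amplitude = 0.25,
                                              corr_length = 3),
                         stage_label = c("low", "high"),
                         stage_amp_multiplier = 1.8,
                         signal_model = c("combined", "ivim", "dki"),
                         seed = 1L) {
  stage_label <- match.arg(stage_label)
  signal_model <- match.arg(signal_model)
  grid_shape <- as.integer(grid_shape)
  assert_that(length(grid_shape) == 3 && all(grid_shape >= 4),
              "grid_shape must be three counts >= 4")
  assert_that(length(voxel_spacing) == 3 && all(voxel_spacing > 0),
              "voxel_spacing must be three positive lengths")
  if (is.null(lesion_center)) lesion_center <- (grid_shape + 1) / 2
  assert_that(length(lesion_center) == 3, "lesion_center must have length 3")
  assert_that(length(lesion_radii) == 3 && all(lesion_radii >= 2),
              "lesion radii must be >= 2 voxels")
  if (any(lesion_center - lesion_radii < 1) ||
      any(lesion_center + lesion_radii > grid_shape)) {
    stop("lesion geometry error: ellipsoid extends outside the grid",
         call. = FALSE)
  }
  for (p in PARAM_NAMES) {
    for (side in list(background_params, lesion_params)) {
      v <- side[[p]]
      assert_that(is.numeric(v) && length(v) %in% 1:2 && all(is.finite(v)),
                  sprintf("parameter '%s' must be a value or a range", p))
    }
  }
  check_rng <- function(pl) {
    rng <- function(p) range(pl[[p]])
    assert_that(all(rng("f") >= 0) && all(rng("f") <= 1), "f must be in [0, 1]")
    assert_that(all(rng("d") > 0), "d must be > 0")
    assert_that(min(rng("dstar")) > max(rng("d")), "dstar must exceed d")
    assert_that(all(rng("md") > 0), "md must be > 0")
    assert_that(all(rng("mk") >= 0), "mk must be >= 0")
    assert_that(all(rng("s0") > 0), "s0 must be > 0")
  }
  check_rng(background_params)
  check_rng(lesion_params)
  het <- modifyList(list(n_blobs = 40, amplitude = 0.25, corr_length = 3),
                    heterogeneity)
  assert_that(het$amplitude >= 0 && het$amplitude < 1,
              "heterogeneity amplitude must be in [0, 1)")
  assert_that(het$corr_length > 0, "correlation length must be > 0")
  structure(list(grid_shape = grid_shape, voxel_spacing = voxel_spacing,
                 lesion_center = lesion_center, lesion_radii = lesion_radii,
                 background_params = background_params,
                 lesion_params = lesion_params, heterogeneity = het,
                 stage_label = stage_label,
                 stage_amp_multiplier = stage_amp_multiplier,
                 signal_model = signal_model, seed = as.integer(seed)),
            class = "phantom_spec")
}

# uniform draw from a value-or-range entry
sample_param <- function(v) if (length(v) == 1L) v else runif(1, v[1], v[2])

# zero-mean Gaussian-blob texture over the lesion voxels, normalized so that
# max |T| = 1 (or all zero for a degenerate configuration)
blob_texture <- function(vox_xyz, center, radii, n_blobs, corr_length) {
  n <- nrow(vox_xyz)
  if (n_blobs < 1L || n == 0L) return(numeric(n))
  cx <- matrix(0, n_blobs, 3)
  for (j in 1:3) {
    cx[, j] <- center[j] + runif(n_blobs, -radii[j], radii[j])
  }
  amp <- sample(c(-1, 1), n_blobs, replace = TRUE) * runif(n_blobs, 0.5, 1)
  tex <- numeric(n)
  for (k in seq_len(n_blobs)) {
    d2 <- (vox_xyz[, 1] - cx[k, 1])^2 + (vox_xyz[, 2] - cx[k, 2])^2 +
      (vox_xyz[, 3] - cx[k, 3])^2
    tex <- tex + amp[k] * exp(-d2 / (2 * corr_length^2))
  }
  tex <- tex - mean(tex)
  m <- max(abs(tex))
  if (m > 0) tex <- tex / m
  tex
}

#' Build a synthetic phantom with ground-truth parameter fields
#'
#' Background voxels take the background parameter values; lesion voxels take
#' the (possibly range-sampled) lesion values with the multiplicative
#' heterogeneity texture applied. High-stage lesions receive the configured
#' amplitude multiplier so that texture features separate the stage groups.
#' Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()]
#' @return a `phantom_truth` list: `spec`, `param_fields` (named list of 3D
#'   arrays), `lesion_mask` (logical 3D array)
#' @export
make_phantom <- function(spec) {
  assert_that(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  dims <- spec$grid_shape
  g <- coord_grids(dims)
  ctr <- spec$lesion_center
  rad <- spec$lesion_radii
  lesion <- ((g$x - ctr[1]) / rad[1])^2 + ((g$y - ctr[2]) / rad[2])^2 +
    ((g$z - ctr[3]) / rad[3])^2 <= 1
  assert_that(any(lesion), "lesion mask is empty")
  idx <- which(lesion)
  vox <- cbind(g$x[idx], g$y[idx], g$z[idx])
  amp <- spec$heterogeneity$amplitude *
    if (spec$stage_label == "high") spec$stage_amp_multiplier else 1
  assert_that(amp < 1, "effective heterogeneity amplitude must stay below 1")

  fields <- with_seed(spec$seed, {
    les <- lapply(spec$lesion_params, sample_param)
    bg <- lapply(spec$background_params, sample_param)
    out <- list()
    for (p in PARAM_NAMES) {
      tex <- blob_texture(vox, ctr, rad, spec$heterogeneity$n_blobs,
                          spec$heterogeneity$corr_length)
      fld <- array(bg[[p]], dim = dims)
      fld[idx] <- les[[p]] * (1 + amp * tex)
      out[[p]] <- fld
    }
    out
  })
  # enforce physical invariants voxelwise (independent textures can collide)
  fields$f <- pmin(pmax(fields$f, 0), 1)
  fields$mk <- pmax(fields$mk, 0)
  fields$dstar <- pmax(fields$dstar, fields$d * (1 + 1e-6))
  structure(list(spec = spec, param_fields = fields, lesion_mask = lesion),
            class = "phantom_truth")
}

#' Reference-tissue ROI for contrast measurements
#'
#' Places a rectangular box in the background compartment (the muscle-like
#' tissue), offset from the lesion along x, for use as the reference region
#' in contrast-to-noise measurements.
#'
#' @param truth a `phantom_truth`
#' @param size box size in voxels (x, y, z)
#' @param gap voxels between lesion boundary and box
#' @return logical 3D array
#' @export
reference_roi_mask <- function(truth, size = c(9, 9, 3), gap = 4) {
  spec <- truth$spec
  dims <- spec$grid_shape
  ctr <- round(spec$lesion_center)
  half <- floor(size / 2)
  for (axis in 1:2) {
    for (dir in c(1, -1)) {
      for (g in unique(c(gap, 2, 1))) {
        cc <- ctr
        cc[axis] <- round(spec$lesion_center[axis] +
                            dir * (spec$lesion_radii[axis] + g + half[axis] + 1))
        lo <- cc - half
        hi <- lo + size - 1
        if (all(lo >= 1) && all(hi <= dims)) {
          box <- array(FALSE, dim = dims)
          box[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
          if (!any(box & truth$lesion_mask)) return(box)
        }
      }
    }
  }
  # fall back to scanning for any background placement (shrinking the box
  # if necessary) on the lesion's central slices
  for (shrink in c(1, 0.6, 0.4)) {
    sz <- pmax(round(size * shrink), 1)
    hf <- floor(sz / 2)
    zlo <- min(max(1, ctr[3] - hf[3]), dims[3] - sz[3] + 1)
    for (x0 in seq(1, dims[1] - sz[1] + 1, by = 2)) {
      for (y0 in seq(1, dims[2] - sz[2] + 1, by = 2)) {
        box <- array(FALSE, dim = dims)
        box[x0:(x0 + sz[1] - 1), y0:(y0 + sz[2] - 1),
            zlo:(zlo + sz[3] - 1)] <- TRUE
        if (!any(box & truth$lesion_mask)) return(box)
      }
    }
  }
  stop("no room for a reference ROI outside the lesion", call. = FALSE)
}
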