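DKI_BVALUES <- c(0, 200, 400, 800, 1500, 2000)

#' Options controlling parametric-map fitting
#'
#' @param ivim_split_b b value separating the perfusion and diffusion
#'   regimes of the segmented IVIM fit (s/mm^2)
#' @param bounds named list of parameter bounds (mm^2/s for diffusivities)
#' @param refine_full_nlls refine segmented estimates by bounded full
#'   nonlinear least squares (default TRUE)
#' @param r2_threshold goodness-of-fit exclusion cutoff (default 0.8)
#' @param r2_level "subject" flags a subject when the ROI-median R^2 of a
#'   model falls below the threshold; "voxel" additionally drops individual
#'   voxels from the fitted masks
#' @return a `fit_options` list
#' @export
fit_options <- function(ivim_split_b = 200,
                        bounds = list(d = c(1e-5, 4e-3),
                                      dstar = c(1e-5, 0.5),
                                      f = c(0, 1),
                                      md = c(1e-5, 4e-3),
                                      mk = c(0, 3)),
                        refine_full_nlls = TRUE,
                        r2_threshold = 0.8,
                        r2_level = c("subject", "voxel")) {
  r2_level <- match.arg(r2_level)
  for (b in bounds) assert_that(length(b) == 2 && b[1] <= b[2],
                                "bounds must be ordered pairs")
  structure(list(ivim_split_b = ivim_split_b, bounds = bounds,
                 refine_full_nlls = refine_full_nlls,
                 r2_threshold = r2_threshold, r2_level = r2_level),
            class = "fit_options")
}

#' Two-point apparent diffusion coefficient
#'
#' ADC = ln(S0/Sb) / b from the b = 0 and (by default) b = 800 s/mm^2
#' signals. Nonpositive signals yield NA (the voxel is flagged invalid in
#' map fitting).
#'
#' @param s0,sb signals at b = 0 and b = `b` (vectors allowed)
#' @param b the nonzero b value (s/mm^2)
#' @return ADC in mm^2/s
#' @export
fit_adc <- function(s0, sb, b = 800) {
  assert_that(is_scalar_number(b) && b > 0, "b must be > 0")
  n <- max(length(s0), length(sb))
  s0 <- rep_len(s0, n)
  sb <- rep_len(sb, n)
  out <- rep(NA_real_, n)
  ok <- is.finite(s0) & is.finite(sb) & s0 > 0 & sb > 0
  out[ok] <- log(s0[ok] / sb[ok]) / b
  out
}

#' Coefficient of determination of a fit
#'
#' R^2 = 1 - SS_res / SS_tot with SS_tot about the observed mean. Returns NA
#' with a warning when the observations have zero variance.
#'
#' @param observed,predicted numeric vectors of equal length >= 3
#' @return R^2 in (-Inf, 1]
#' @export
goodness_of_fit <- function(observed, predicted) {
  assert_that(length(observed) == length(predicted) && length(observed) >= 3,
              "observed and predicted must have equal length >= 3")
  sst <- sum((observed - mean(observed))^2)
  if (sst <= 0) {
    warning("zero total variance: R^2 undefined", call. = FALSE)
    return(NA_real_)
  }
  1 - sum((observed - predicted)^2) / sst
}

# shared single-voxel wrapper plumbing
as_signal_matrix <- function(signals) {
  if (is.matrix(signals)) signals else matrix(signals, nrow = 1)
}

#' Segmented IVIM fit with optional full-NLLS refinement
#'
#' Fits S(b) = S0[(1-f) e^(-bD) + f e^(-b(D+D*))] with S0 fixed at the
#' measured b = 0 signal: D and f come from a log-linear fit over
#' b >= `ivim_split_b`, D* from a one-dimensional search on the full
#' residual, and (by default) all three parameters are polished by bounded
#' Levenberg-Marquardt.
#'
#' @param signals per-b signal values (b <= 800 s/mm^2 scheme)
#' @param b b values matching `signals`
#' @param options a [fit_options()]
#' @return list with `d`, `dstar`, `f`, `r2`, `valid`, `converged`
#' @export
fit_ivim <- function(signals, b, options = fit_options()) {
  b <- as.numeric(b)
  assert_that(length(unique(b)) >= 4, "need at least 4 distinct b values")
  assert_that(b[1] == 0, "the first b value must be 0")
  assert_that(options$ivim_split_b > min(b) && options$ivim_split_b < max(b),
              "ivim_split_b must lie strictly inside the b range")
  S <- as_signal_matrix(signals)
  fit <- ivim_fit_cpp(S, b, options$ivim_split_b,
                      options$bounds$d, options$bounds$dstar,
                      options$bounds$f, options$refine_full_nlls,
                      300L, 1e-12)
  if (nrow(S) == 1L) lapply(fit, `[`, 1L) else fit
}

#' Diffusion-kurtosis fit
#'
#' Fits S(b) = S0 e^(-b MD + b^2 MD^2 MK/6) over the 6-b-value kurtosis
#' scheme (0, 200, 400, 800, 1500, 2000 s/mm^2 by default), initialized by
#' linear least squares on ln(S/S0) and refined by bounded
#' Levenberg-Marquardt.
#'
#' @inheritParams fit_ivim
#' @return list with `md`, `mk`, `r2`, `valid`, `converged`
#' @export
fit_dki <- function(signals, b, options = fit_options()) {
  b <- as.numeric(b)
  assert_that(length(unique(b)) >= 3, "need at least 3 distinct b values")
  assert_that(b[1] == 0, "the first b value must be 0")
  S <- as_signal_matrix(signals)
  fit <- dki_fit_cpp(S, b, options$bounds$md, options$bounds$mk,
                     options$refine_full_nlls, 300L, 1e-12)
  if (nrow(S) == 1L) lapply(fit, `[`, 1L) else fit
}

#' Voxelwise parametric-map fitting over a series
#'
#' Applies the ADC, IVIM and DKI fits voxelwise over `mask` (or the whole
#' grid). IVIM uses the b <= 800 s/mm^2 entries of the scheme; DKI the
#' 6-value kurtosis subset; ADC the (0, 800) pair. Voxels with nonpositive
#' signals are flagged invalid and excluded from the fitted masks. With
#' `r2_level = "voxel"` voxels whose model R^2 falls below the threshold are
#' additionally dropped; at subject level the whole fit is flagged for
#' exclusion when an ROI-median R^2 falls below the threshold.
#'
#' @param series a [dwi_series()]
#' @param options a [fit_options()]
#' @param mask optional logical 3D array restricting the fit
#' @return a `parametric_map_set`: `maps` (adc, d, dstar, f, md, mk), `r2`
#'   (ivim, dki), per-model valid masks, `fit_mask`, subject-level exclusion
#'   flags, and the voxel spacing
#' @export
fit_map_set <- function(series, options = fit_options(), mask = NULL) {
  assert_that(inherits(series, "dwi_series"), "series must be a dwi_series")
  dims <- dim(series$volumes)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dim = dims)
  assert_that(all(dim(mask) == dims), "mask must match the series grid")
  assert_that(any(mask), "mask is empty")
  b <- series$scheme$b
  assert_that(all(c(0, 800) %in% b), "scheme must contain b = 0 and b = 800")
  assert_that(all(DKI_BVALUES %in% b),
              "scheme must contain the 6 kurtosis b values")
  idx <- which(mask)
  V <- matrix(series$volumes, nrow = prod(dims))
  S <- V[idx, , drop = FALSE]

  ivim_cols <- which(b <= 800)
  dki_cols <- match(DKI_BVALUES, b)
  ivim <- ivim_fit_cpp(S[, ivim_cols, drop = FALSE], b[ivim_cols],
                       options$ivim_split_b, options$bounds$d,
                       options$bounds$dstar, options$bounds$f,
                       options$refine_full_nlls, 300L, 1e-12)
  dki <- dki_fit_cpp(S[, dki_cols, drop = FALSE], b[dki_cols],
                     options$bounds$md, options$bounds$mk,
                     options$refine_full_nlls, 300L, 1e-12)
  adc <- fit_adc(S[, which(b == 0)[1]], S[, which(b == 800)[1]])

  blank <- array(NA_real_, dim = dims)
  put <- function(v) { a <- blank; a[idx] <- v; a }
  put_mask <- function(v) { a <- array(FALSE, dim = dims); a[idx] <- v; a }

  adc_valid <- !is.na(adc)
  ivim_valid <- as.logical(ivim$valid)
  dki_valid <- as.logical(dki$valid)
  thr <- options$r2_threshold
  if (options$r2_level == "voxel") {
    ivim_valid <- ivim_valid & !is.na(ivim$r2) & ivim$r2 >= thr
    dki_valid <- dki_valid & !is.na(dki$r2) & dki$r2 >= thr
  }
  med_r2 <- c(ivim = median(ivim$r2, na.rm = TRUE),
              dki = median(dki$r2, na.rm = TRUE))
  excluded <- any(is.na(med_r2)) || any(med_r2 < thr)

  structure(list(
    maps = list(adc = put(adc), d = put(ivim$d), dstar = put(ivim$dstar),
                f = put(ivim$f), md = put(dki$md), mk = put(dki$mk)),
    r2 = list(ivim = put(ivim$r2), dki = put(dki$r2)),
    valid = list(adc = put_mask(adc_valid), ivim = put_mask(ivim_valid),
                 dki = put_mask(dki_valid)),
    fit_mask = put_mask(adc_valid & ivim_valid & dki_valid),
    median_r2 = med_r2, excluded = excluded,
    spacing = series$spacing, options = options
  ), class = "parametric_map_set")
}

# which valid-mask applies to each map
MAP_MODEL <- c(adc = "adc", d = "ivim", dstar = "ivim", f = "ivim",
               md = "dki", mk = "dki")
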