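#' A multi-b-value DWI series
#'
#' One subject/sequence 4D magnitude image stack with its b-value scheme and
#' acquisition metadata. Volumes are stored as a (x, y, z, b-index) array of
#' nonnegative magnitude values, one (averaged) volume per scheme entry.
#'
#' @param volumes 4D numeric array
#' @param scheme a [bvalue_scheme()]
#' @param sequence_label "S1", "S2" or "S3"
#' @param af_profile optional [af_profile()] attached to the series
#' @param subject_id identifier string
#' @param spacing voxel spacing in mm
#' @return a `dwi_series` list
#' @export
dwi_series <- function(volumes, scheme, sequence_label = "S1",
                       af_profile = NULL, subject_id = "sub001",
                       spacing = c(1, 1, 1)) {
  assert_that(length(dim(volumes)) == 4L, "volumes must be a 4D array")
  assert_that(inherits(scheme, "bvalue_scheme"), "scheme must be a bvalue_scheme")
  assert_that(dim(volumes)[4] == nrow(scheme),
              "volume count must equal the number of scheme entries")
  assert_that(all(volumes >= 0, na.rm = TRUE),
              "magnitude volumes must be nonnegative")
  assert_that(sequence_label %in% c("S1", "S2", "S3"),
              "sequence_label must be S1, S2 or S3")
  structure(list(volumes = volumes, scheme = scheme,
                 sequence_label = sequence_label, af_profile = af_profile,
                 subject_id = subject_id, spacing = spacing),
            class = "dwi_series")
}

# noiseless signal ratio S(b)/S0 for one b over parameter fields
signal_ratio <- function(model, b, p) {
  switch(model,
    ivim = (1 - p$f) * exp(-b * p$d) + p$f * exp(-b * (p$d + p$dstar)),
    dki = exp(-b * p$md + b^2 * p$md^2 * p$mk / 6),
    combined = p$f * exp(-b * p$dstar) +
      (1 - p$f) * exp(-b * p$md + b^2 * p$md^2 * p$mk / 6),
    stop("unknown signal model: ", model, call. = FALSE))
}

#' Forward-model noiseless DWI signals from a phantom
#'
#' Evaluates the phantom's signal model voxelwise at every b value of the
#' scheme. In `ivim` mode the bi-exponential model
#' S = S0[(1-f) e^(-bD) + f e^(-b(D+D*))] is used; in `dki` mode the kurtosis
#' model S = S0 e^(-b MD + b^2 MD^2 MK / 6); `combined` mode superimposes the
#' perfusion compartment on the kurtosis decay. S(b = 0) equals S0 exactly in
#' all modes. If the quadratic kurtosis term would push a signal above S0 at
#' large b, the affected ratios are clipped to 1 with a warning and the
#' returned series carries a `clipped` attribute.
#'
#' @param truth a `phantom_truth` from [make_phantom()]
#' @param scheme a [bvalue_scheme()]
#' @param sequence_label,subject_id metadata for the series
#' @return a noiseless [dwi_series()]
#' @export
simulate_signal <- function(truth, scheme = default_bvalue_scheme(),
                            sequence_label = "S1", subject_id = "sub001") {
  assert_that(inherits(truth, "phantom_truth"), "truth must be a phantom_truth")
  p <- truth$param_fields
  dims <- truth$spec$grid_shape
  nb <- nrow(scheme)
  vols <- array(0, dim = c(dims, nb))
  model <- truth$spec$signal_model
  clipped <- FALSE
  for (k in seq_len(nb)) {
    ratio <- signal_ratio(model, scheme$b[k], p)
    if (model %in% c("dki", "combined") && any(ratio > 1)) {
      clipped <- TRUE
      ratio <- pmin(ratio, 1)
    }
    vols[, , , k] <- p$s0 * ratio
  }
  if (clipped) {
    warning("kurtosis term exceeded S0 at high b; signals clipped to S0",
            call. = FALSE)
  }
  out <- dwi_series(vols, scheme, sequence_label = sequence_label,
                    subject_id = subject_id,
                    spacing = truth$spec$voxel_spacing)
  attr(out, "clipped") <- clipped
  out
}

#' Apply acceleration-factor effects to a noiseless series
#'
#' Scales all signals by the T1-saturation factor 1 - exp(-TR/T1) implied by
#' the profile's repetition time, and attaches the profile so that
#' [add_rician_noise()] picks up its noise-scale multiplier. Applied before
#' noise.
#'
#' @param series a [dwi_series()]
#' @param profile an [af_profile()]
#' @return the scaled series with `af_profile` attached
#' @export
emulate_af <- function(series, profile) {
  assert_that(inherits(series, "dwi_series"), "series must be a dwi_series")
  assert_that(inherits(profile, "af_profile"), "profile must be an af_profile")
  factor <- if (profile$t1_ms <= 0) 1 else 1 - exp(-profile$tr_ms / profile$t1_ms)
  series$volumes <- series$volumes * factor
  series$af_profile <- profile
  series
}

#' Add averaged Rician magnitude noise
#'
#' For every b entry, `n_averages` independent Rician realizations (the
#' magnitude of a complex Gaussian with the true signal as real part and
#' per-channel standard deviation `sigma` times the profile's noise scale)
#' are generated and averaged, emulating on-scanner averaging. `sigma = 0`
#' returns the input unchanged. Deterministic given `seed`.
#'
#' @param series a [dwi_series()]
#' @param sigma per-channel noise standard deviation (signal units), >= 0
#' @param seed RNG seed
#' @return a noisy [dwi_series()]
#' @export
add_rician_noise <- function(series, sigma, seed = 1L) {
  assert_that(inherits(series, "dwi_series"), "series must be a dwi_series")
  assert_that(is_scalar_number(sigma) && sigma >= 0, "sigma must be >= 0")
  if (sigma == 0) return(series)
  scale <- if (!is.null(series$af_profile)) series$af_profile$sigma_scale else 1
  s <- sigma * scale
  dims <- dim(series$volumes)
  nvox <- prod(dims[1:3])
  nb <- dims[4]
  out <- series$volumes
  with_seed(seed, {
    for (k in seq_len(nb)) {
      m <- series$scheme$n_averages[k]
      true_sig <- as.numeric(series$volumes[, , , k])
      acc <- numeric(nvox)
      for (j in seq_len(m)) {
        re <- true_sig + rnorm(nvox, 0, s)
        im <- rnorm(nvox, 0, s)
        acc <- acc + sqrt(re * re + im * im)
      }
      out[, , , k] <- acc / m
    }
  })
  series$volumes <- out
  series
}
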