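#' Multi-b-value acquisition scheme
#'
#' A b-value scheme pairs each diffusion weighting b (s/mm^2) with the number
#' of repeated acquisitions averaged at that weighting. b values must be
#' strictly increasing and start at b = 0; every entry has at least one
#' average.
#'
#' @param b numeric vector of diffusion weightings (s/mm^2)
#' @param n_averages integer vector of per-b average counts
#' @return a `bvalue_scheme` data frame with columns `b` and `n_averages`
#' @export
bvalue_scheme <- function(b, n_averages = rep(1L, length(b))) {
  b <- as.numeric(b)
  n_averages <- as.integer(n_averages)
  assert_that(length(b) >= 2L, "a scheme needs at least two b values")
  assert_that(length(n_averages) == length(b),
              "b and n_averages must have equal length")
  assert_that(b[1] == 0, "the first b value must be 0")
  assert_that(all(diff(b) > 0), "b values must be strictly increasing")
  assert_that(all(n_averages >= 1L), "all n_averages must be >= 1")
  structure(data.frame(b = b, n_averages = n_averages),
            class = c("bvalue_scheme", "data.frame"))
}

#' Default 11-b-value scheme
#'
#' The pelvic multi-b-value protocol emulated by the synthetic cohort:
#' b = 0, 10, 20, 40, 80, 150, 200, 400, 800, 1500, 2000 s/mm^2 with
#' 1, 1, 1, 1, 1, 1, 2, 2, 2, 4, 6 averages.
#' @return a [bvalue_scheme()]
#' @export
default_bvalue_scheme <- function() {
  bvalue_scheme(c(0, 10, 20, 40, 80, 150, 200, 400, 800, 1500, 2000),
                c(1, 1, 1, 1, 1, 1, 2, 2, 2, 4, 6))
}

#' Acceleration-factor profile
#'
#' Describes how a simultaneous-multislice acceleration factor is emulated:
#' the repetition time drives a T1-saturation scaling 1 - exp(-TR/T1), and a
#' multiplicative noise-scale factor (relative to AF = 1) inflates the Rician
#' noise level.
#'
#' @param af acceleration factor, 1, 2 or 3
#' @param tr_ms repetition time in ms
#' @param t1_ms assumed tissue T1 in ms
#' @param sigma_scale noise-scale multiplier relative to AF = 1
#' @return an `af_profile` list
#' @export
af_profile <- function(af, tr_ms, t1_ms = 1500, sigma_scale = 1) {
  assert_that(af %in% 1:3, "af must be 1, 2 or 3")
  assert_that(is_scalar_number(tr_ms) && tr_ms > 0, "tr_ms must be > 0")
  assert_that(is_scalar_number(t1_ms) && t1_ms >= 0, "t1_ms must be >= 0")
  assert_that(is_scalar_number(sigma_scale) && sigma_scale > 0,
              "sigma_scale must be > 0")
  if (af == 1) assert_that(sigma_scale == 1, "af = 1 implies sigma_scale = 1")
  else assert_that(sigma_scale >= 1, "sigma_scale must be >= 1 for af > 1")
  structure(list(af = as.integer(af), tr_ms = tr_ms, t1_ms = t1_ms,
                 sigma_scale = sigma_scale),
            class = "af_profile")
}

#' Default S1-S3 acceleration profiles
#'
#' TRs of 4700, 2500 and 2000 ms for AF 1, 2 and 3, a common assumed tissue
#' T1, and noise-scale multipliers of 1.0, 1.1 and 1.3.
#'
#' @param t1_ms assumed tissue T1 (ms)
#' @param sigma_scales noise-scale multipliers for S1, S2, S3
#' @return named list of three [af_profile()]s (S1, S2, S3)
#' @export
default_af_profiles <- function(t1_ms = 900, sigma_scales = c(1, 1.1, 1.3)) {
  list(S1 = af_profile(1, 4700, t1_ms, sigma_scales[1]),
       S2 = af_profile(2, 2500, t1_ms, sigma_scales[2]),
       S3 = af_profile(3, 2000, t1_ms, sigma_scales[3]))
}
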