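#' Base phantom specification for cohort simulation
#'
#' Like [phantom_spec()] but with lesion parameters given as sampling ranges,
#' so that each simulated subject draws its own tumor biology. Ranges span
#' typical cervical-tumor values: D 0.7-1.1, MD 1.0-1.5 (10^-3 mm^2/s),
#' D* 8-16 (10^-3 mm^2/s), f 0.06-0.14, MK 0.6-1.1, S0 350-450.
#'
#' @param ... overrides passed to [phantom_spec()]
#' @return a `phantom_spec`
#' @export
cohort_base_spec <- function(...) {
  args <- list(...)
  defaults <- list(
    lesion_params = list(s0 = c(350, 450), d = c(0.7e-3, 1.1e-3),
                         dstar = c(8e-3, 16e-3), f = c(0.06, 0.14),
                         md = c(1.0e-3, 1.5e-3), mk = c(0.6, 1.1))
  )
  do.call(phantom_spec, modifyList(defaults, args))
}

# Build one cohort subject: a phantom plus its three DWI series.
# The three series share the one phantom (same anatomy) and differ only in
# acceleration emulation and noise realization. Sub-seeds are derived
# deterministically from (seed, subject index, stream).
cohort_subject <- function(seed, i, stage, base_spec, af_profiles, sigma,
                           scheme, stage_effect, radius_jitter,
                           keep_series = TRUE) {
  subject_id <- sprintf("sub%03d", i)
  spec_i <- with_seed(derive_seed(seed, i, 0L), {
    les <- lapply(base_spec$lesion_params, sample_param)
    radii <- base_spec$lesion_radii *
      runif(3, 1 - radius_jitter, 1 + radius_jitter)
    if (stage == "high") radii <- radii * stage_effect$radius
    radii <- pmax(radii, 2)
    phantom_spec(grid_shape = base_spec$grid_shape,
                 voxel_spacing = base_spec$voxel_spacing,
                 lesion_center = base_spec$lesion_center,
                 lesion_radii = radii,
                 background_params = base_spec$background_params,
                 lesion_params = les,
                 heterogeneity = base_spec$heterogeneity,
                 stage_label = stage,
                 stage_amp_multiplier = stage_effect$amplitude,
                 signal_model = base_spec$signal_model,
                 seed = derive_seed(seed, i, 1L))
  })
  truth <- make_phantom(spec_i)
  clean <- simulate_signal(truth, scheme, subject_id = subject_id)
  series <- list()
  for (s in 1:3) {
    lab <- names(af_profiles)[s]
    ser <- clean
    ser$sequence_label <- lab
    ser <- emulate_af(ser, af_profiles[[s]])
    ser <- add_rician_noise(ser, sigma, seed = derive_seed(seed, i, 10L + s))
    if (keep_series) series[[lab]] <- ser else series[[lab]] <- NULL
  }
  list(subject_id = subject_id, stage = stage, truth = truth,
       series = if (keep_series) series else NULL)
}

#' Simulate a two-group synthetic cohort
#'
#' Generates `n_low + n_high` subjects. Each subject has one ground-truth
#' phantom (lesion parameters resampled from the base specification's ranges)
#' and three DWI series S1-S3 differing only in acceleration emulation and
#' noise realization. High-stage subjects receive larger lesion radii and a
#' larger heterogeneity amplitude, controlled by `stage_effect`; setting both
#' multipliers to 1 makes the groups exchangeable.
#'
#' @param n_low,n_high group sizes (>= 1)
#' @param base_spec a [cohort_base_spec()] (or any `phantom_spec`)
#' @param af_profiles named list of three [af_profile()]s (S1, S2, S3)
#' @param sigma Rician noise scale at AF = 1 (signal units)
#' @param seed master seed; per-subject/per-sequence sub-seeds are derived
#'   deterministically from it
#' @param stage_effect list with `amplitude` and `radius` multipliers applied
#'   to high-stage lesions
#' @param radius_jitter relative half-width of the per-subject radius draw
#' @param scheme acquisition scheme
#' @return list with `subjects` (each holding `subject_id`, `stage`, `truth`,
#'   and the three `series`) and a `metadata` data frame
#' @export
make_cohort <- function(n_low = 12, n_high = 28,
                        base_spec = cohort_base_spec(),
                        af_profiles = default_af_profiles(),
                        sigma = 6, seed = 1L,
                        stage_effect = list(amplitude = 1.8, radius = 1.25),
                        radius_jitter = 0.15,
                        scheme = default_bvalue_scheme()) {
  assert_that(n_low >= 1 && n_high >= 1, "both group counts must be >= 1")
  assert_that(length(af_profiles) == 3, "three AF profiles are required")
  n <- n_low + n_high
  stages <- rep(c("low", "high"), c(n_low, n_high))
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    subjects[[i]] <- cohort_subject(seed, i, stages[i], base_spec,
                                    af_profiles, sigma, scheme,
                                    stage_effect, radius_jitter)
  }
  metadata <- data.frame(
    subject_id = rep(vapply(subjects, `[[`, "", "subject_id"), each = 3),
    stage = rep(stages, each = 3),
    sequence = rep(names(af_profiles), n),
    stringsAsFactors = FALSE
  )
  list(subjects = subjects, metadata = metadata)
}
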