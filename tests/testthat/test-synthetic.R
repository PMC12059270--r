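small_spec <- function(...) {
  phantom_spec(grid_shape = c(24, 24, 12), lesion_center = c(12, 12, 6),
               lesion_radii = c(5, 5, 3), ...)
}

test_that("b-value scheme enforces its invariants", {
  sch <- default_bvalue_scheme()
  expect_equal(nrow(sch), 11)
  expect_equal(sch$b[1], 0)
  expect_equal(sum(sch$n_averages), 22)
  expect_error(bvalue_scheme(c(10, 20)), "first b")
  expect_error(bvalue_scheme(c(0, 20, 20)), "increasing")
  expect_error(bvalue_scheme(c(0, 20), c(1, 0)), "n_averages")
})

test_that("phantom construction is deterministic and respects the texture", {
  sp <- small_spec(heterogeneity = list(amplitude = 0), seed = 11)
  tr <- make_phantom(sp)
  expect_true(all(tr$param_fields$d[tr$lesion_mask] == sp$lesion_params$d))
  expect_identical(make_phantom(sp), tr)

  sp2 <- small_spec(
    lesion_params = list(s0 = 400, d = 1.0e-3, dstar = 12e-3, f = 0.1,
                         md = 1.2e-3, mk = 0.85),
    heterogeneity = list(amplitude = 0.1, n_blobs = 30, corr_length = 3),
    seed = 5)
  tr2 <- make_phantom(sp2)
  dv <- tr2$param_fields$d[tr2$lesion_mask]
  expect_gte(length(dv), 250)
  expect_true(all(dv >= 0.9e-3 & dv <= 1.1e-3))
  expect_lt(abs(mean(dv) / 1.0e-3 - 1), 0.02)
  fv <- tr2$param_fields$f
  expect_true(all(fv >= 0 & fv <= 1))
  expect_true(all(tr2$param_fields$dstar > tr2$param_fields$d))
})

test_that("a lesion outside the grid is rejected with a geometry error", {
  expect_error(phantom_spec(grid_shape = c(16, 16, 8),
                            lesion_center = c(14, 8, 4),
                            lesion_radii = c(5, 5, 2)),
               "geometry")
})

test_that("forward signals follow the closed-form models", {
  b <- c(0, 800)
  sp <- small_spec(signal_model = "ivim",
                   lesion_params = list(s0 = 100, d = 1e-3, dstar = 10e-3,
                                        f = 0, md = 1.2e-3, mk = 0.85),
                   background_params = list(s0 = 100, d = 1e-3, dstar = 10e-3,
                                            f = 0, md = 1.2e-3, mk = 0.85))
  tr <- make_phantom(sp)
  ser <- simulate_signal(tr, bvalue_scheme(b))
  expect_equal(ser$volumes[1, 1, 1, 1], 100)
  expect_equal(ser$volumes[1, 1, 1, 2] / 100, exp(-0.8), tolerance = 1e-12)

  spd <- small_spec(signal_model = "dki",
                    lesion_params = list(s0 = 50, d = 1e-3, dstar = 10e-3,
                                         f = 0.1, md = 1e-3, mk = 1),
                    background_params = list(s0 = 50, d = 1e-3, dstar = 10e-3,
                                             f = 0.1, md = 1e-3, mk = 1))
  trd <- make_phantom(spd)
  serd <- simulate_signal(trd, bvalue_scheme(c(0, 2000)))
  expect_equal(serd$volumes[1, 1, 1, 2] / 50, exp(-2 + 4 / 6),
               tolerance = 1e-12)
  # any mode: S(b = 0) = S0 exactly
  expect_true(all(serd$volumes[, , , 1] == trd$param_fields$s0))
})

test_that("an overlarge kurtosis term is clipped with a warning", {
  sp <- small_spec(signal_model = "dki",
                   lesion_params = list(s0 = 100, d = 1e-3, dstar = 10e-3,
                                        f = 0.1, md = 3e-3, mk = 3),
                   background_params = list(s0 = 100, d = 1e-3, dstar = 10e-3,
                                            f = 0.1, md = 3e-3, mk = 3))
  tr <- make_phantom(sp)
  expect_warning(ser <- simulate_signal(tr, default_bvalue_scheme()),
                 "clipped")
  expect_true(attr(ser, "clipped"))
  expect_true(all(ser$volumes[, , , 11] <= tr$param_fields$s0))
})

test_that("T1-saturation scaling matches the closed form and attaches the profile", {
  sp <- small_spec()
  tr <- make_phantom(sp)
  ser <- simulate_signal(tr, bvalue_scheme(c(0, 800)))
  for (case in list(c(4700, 1500), c(2000, 1500))) {
    prof <- af_profile(1, case[1], case[2], 1)
    out <- emulate_af(ser, prof)
    expect_equal(out$volumes / ser$volumes,
                 array(1 - exp(-case[1] / case[2]), dim = dim(ser$volumes)),
                 tolerance = 1e-12)
  }
  # t1 -> 0 limit leaves signals unchanged
  out0 <- emulate_af(ser, af_profile(1, 2000, 0, 1))
  expect_identical(out0$volumes, ser$volumes)
  expect_equal(out0$af_profile$tr_ms, 2000)
})

test_that("Rician noise has the analytic zero-signal mean and averaging law", {
  sch <- bvalue_scheme(c(0, 800), c(1, 4))
  vols <- array(0, c(48, 48, 48, 2))
  ser <- dwi_series(vols, sch)
  expect_identical(add_rician_noise(ser, 0, seed = 1), ser)
  noisy <- add_rician_noise(ser, 1, seed = 7)
  expect_equal(mean(noisy$volumes[, , , 1]), sqrt(pi / 2), tolerance = 0.01)

  vols2 <- array(100, c(30, 30, 30, 2))
  ser2 <- dwi_series(vols2, sch)
  noisy2 <- add_rician_noise(ser2, 2, seed = 8)
  ratio <- sd(noisy2$volumes[, , , 2]) / sd(noisy2$volumes[, , , 1])
  expect_equal(ratio, 0.5, tolerance = 0.1)
  expect_error(add_rician_noise(ser2, -1), "sigma")
  # determinism
  expect_identical(add_rician_noise(ser2, 2, seed = 8)$volumes,
                   noisy2$volumes)
})

test_that("cohort generation has the right shape and is deterministic", {
  base <- cohort_base_spec(grid_shape = c(16, 16, 10),
                          lesion_center = c(8, 8, 5),
                          lesion_radii = c(3.5, 3.5, 2.5))
  co <- make_cohort(n_low = 12, n_high = 28, base_spec = base, sigma = 4,
                    seed = 2, radius_jitter = 0.1,
                    scheme = bvalue_scheme(c(0, 800), c(1, 1)))
  expect_length(co$subjects, 40)
  expect_equal(sum(co$metadata$stage == "low"), 12 * 3)
  expect_equal(nrow(co$metadata), 120)
  expect_length(co$subjects[[1]]$series, 3)
  co2 <- make_cohort(n_low = 12, n_high = 28, base_spec = base, sigma = 4,
                     seed = 2, radius_jitter = 0.1,
                     scheme = bvalue_scheme(c(0, 800), c(1, 1)))
  expect_identical(co2$subjects[[5]]$series$S2$volumes,
                   co$subjects[[5]]$series$S2$volumes)
  # three series per subject share one phantom
  expect_identical(co$subjects[[3]]$truth$lesion_mask,
                   co$subjects[[3]]$truth$lesion_mask)
})

test_that("a unit stage-effect multiplier leaves the groups exchangeable", {
  base <- cohort_base_spec(grid_shape = c(12, 12, 8),
                          lesion_center = c(6, 6, 4),
                          lesion_radii = c(2.5, 2.5, 2))
  pvals <- vapply(1:20, function(s) {
    n <- 8
    stages <- rep(c("low", "high"), each = n)
    means <- vapply(seq_len(2 * n), function(i) {
      sub <- radstab:::cohort_subject(s, i, stages[i], base,
                                      default_af_profiles(), 0,
                                      bvalue_scheme(c(0, 800)),
                                      list(amplitude = 1, radius = 1), 0.1,
                                      keep_series = FALSE)
      mean(sub$truth$param_fields$d[sub$truth$lesion_mask])
    }, 0)
    t.test(means[stages == "low"], means[stages == "high"])$p.value
  }, 0)
  expect_gte(mean(pvals > 0.05), 0.9)
})
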