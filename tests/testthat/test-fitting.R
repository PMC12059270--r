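ivim_signal <- function(b, s0, d, ds, f) {
  s0 * ((1 - f) * exp(-b * d) + f * exp(-b * (d + ds)))
}
dki_signal <- function(b, s0, md, mk) {
  s0 * exp(-b * md + b^2 * md^2 * mk / 6)
}
B9 <- c(0, 10, 20, 40, 80, 150, 200, 400, 800)
B6 <- c(0, 200, 400, 800, 1500, 2000)

test_that("ADC follows the closed-form log ratio", {
  expect_equal(fit_adc(100, 44.9329), 1.0e-3, tolerance = 1e-6)
  expect_equal(fit_adc(100, 100 * exp(-0.8)), 1.0e-3, tolerance = 1e-12)
  expect_equal(fit_adc(100, 100), 0)
  expect_equal(fit_adc(100, 100 * exp(-1.6)), 2.0e-3, tolerance = 1e-12)
  expect_true(is.na(fit_adc(0, 10)))
  expect_true(is.na(fit_adc(10, -1)))
})

test_that("R-squared matches direct evaluation and flags degenerate input", {
  expect_equal(goodness_of_fit(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(goodness_of_fit(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(goodness_of_fit(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_warning(r <- goodness_of_fit(c(2, 2, 2), c(1, 2, 3)), "variance")
  expect_true(is.na(r))
})

test_that("noiseless IVIM signals are recovered to high accuracy", {
  fit <- fit_ivim(ivim_signal(B9, 100, 1.0e-3, 10e-3, 0.10), B9)
  expect_equal(fit$d, 1.0e-3, tolerance = 1e-3)
  expect_equal(fit$dstar, 10e-3, tolerance = 1e-3)
  expect_equal(fit$f, 0.10, tolerance = 1e-3)
  expect_gte(fit$r2, 0.999999)

  # mono-exponential degenerate case
  f0 <- fit_ivim(ivim_signal(B9, 80, 1.2e-3, 10e-3, 0), B9)
  expect_lt(f0$f, 1e-3)
  expect_equal(f0$d, 1.2e-3, tolerance = 1e-4)

  # fast pseudodiffusion regime: flat likelihood in D*
  ff <- fit_ivim(ivim_signal(B9, 120, 0.9e-3, 100e-3, 0.15), B9)
  expect_equal(ff$d, 0.9e-3, tolerance = 1e-3)
  expect_equal(ff$f, 0.15, tolerance = 1e-3)
  expect_equal(ff$dstar, 100e-3, tolerance = 1e-2)
})

test_that("noiseless DKI signals are recovered to near machine accuracy", {
  fit <- fit_dki(dki_signal(B6, 90, 1.2e-3, 0.8), B6)
  expect_equal(fit$md, 1.2e-3, tolerance = 1e-6)
  expect_equal(fit$mk, 0.8, tolerance = 1e-6)

  g <- fit_dki(dki_signal(B6, 90, 1.0e-3, 0), B6)
  expect_lt(g$mk, 1e-6)
  expect_equal(g$md, 1.0e-3, tolerance = 1e-6)

  h <- fit_dki(dki_signal(B6, 90, 1.0e-3, 1.0), B6)
  pred <- dki_signal(2000, 90, h$md, h$mk)
  expect_equal(pred / 90, exp(-2 + 4 / 6), tolerance = 1e-6)
})

test_that("segmented-plus-refined IVIM agrees with a dense grid-search oracle", {
  set.seed(42)
  for (rep in 1:20) {
    d <- runif(1, 0.5e-3, 1.8e-3)
    ds <- exp(runif(1, log(6e-3), log(60e-3)))
    f <- runif(1, 0.04, 0.25)
    sig <- ivim_signal(B9, 100, d, ds, f)
    fit <- fit_ivim(sig, B9)
    dg <- seq(0.4e-3, 2.0e-3, length.out = 60)
    dsg <- exp(seq(log(4e-3), log(80e-3), length.out = 60))
    fg <- seq(0.02, 0.3, length.out = 60)
    best <- c(NA, NA, NA); best_sse <- Inf
    for (dd in dg) {
      A <- 100 * exp(-B9 * dd)
      for (dss in dsg) {
        B <- 100 * exp(-B9 * (dd + dss))
        # SSE is quadratic in f: evaluate the whole f grid at once
        D <- B - A
        r0 <- sig - A
        sse <- sum(r0^2) - 2 * fg * sum(r0 * D) + fg^2 * sum(D^2)
        k <- which.min(sse)
        if (sse[k] < best_sse) { best_sse <- sse[k]; best <- c(dd, dss, fg[k]) }
      }
    }
    # the refined fit is at least as good as the dense grid optimum, and both
    # sit within grid resolution of the true parameters
    sse_fit <- sum((sig - ivim_signal(B9, 100, fit$d, fit$dstar, fit$f))^2)
    expect_lte(sse_fit, best_sse * (1 + 1e-9) + 1e-12)
    expect_lt(abs(fit$d - d), diff(dg[1:2]))
    expect_lt(abs(log(fit$dstar) - log(ds)), diff(log(dsg[1:2])))
    expect_lt(abs(fit$f - f), diff(fg[1:2]))
    expect_lt(abs(best[1] - d), 2 * diff(dg[1:2]))
    expect_lt(abs(best[3] - f), 2 * diff(fg[1:2]))
  }
})

test_that("parameters are invariant to global signal scaling", {
  sig <- ivim_signal(B9, 100, 1.1e-3, 15e-3, 0.12)
  f1 <- fit_ivim(sig, B9)
  f2 <- fit_ivim(sig * 7.3, B9)
  expect_equal(f1$d, f2$d, tolerance = 1e-12)
  expect_equal(f1$dstar, f2$dstar, tolerance = 1e-10)
  expect_equal(f1$f, f2$f, tolerance = 1e-12)
  sig6 <- dki_signal(B6, 55, 1.3e-3, 0.9)
  g1 <- fit_dki(sig6, B6)
  g2 <- fit_dki(sig6 * 0.013, B6)
  expect_equal(g1$md, g2$md, tolerance = 1e-12)
  expect_equal(g1$mk, g2$mk, tolerance = 1e-10)
})

test_that("errors degrade monotonically with noise, D* fastest", {
  set.seed(99)
  sigma_levels <- c(0, 2, 6)
  n <- 400
  err <- matrix(NA, 3, 3, dimnames = list(NULL, c("adc", "d", "dstar")))
  truth <- c(d = 1.0e-3, ds = 12e-3, f = 0.1)
  clean <- ivim_signal(B9, 100, truth["d"], truth["ds"], truth["f"])
  adc_true <- log(clean[1] / clean[B9 == 800]) / 800
  for (si in seq_along(sigma_levels)) {
    s <- sigma_levels[si]
    S <- matrix(rep(clean, each = n), n)
    if (s > 0) {
      S <- sqrt((S + matrix(rnorm(n * 9, 0, s), n))^2 +
                  matrix(rnorm(n * 9, 0, s), n)^2)
    }
    fit <- fit_ivim(S, B9)
    err[si, "d"] <- median(abs(fit$d - truth["d"]) / truth["d"])
    err[si, "dstar"] <- median(abs(fit$dstar - truth["ds"]) / truth["ds"])
    adc <- fit_adc(S[, 1], S[, B9 == 800])
    err[si, "adc"] <- median(abs(adc - adc_true) / adc_true)
  }
  expect_true(all(diff(err[, "dstar"]) > 0))
  expect_true(all(diff(err[, "adc"]) >= 0))
  # pseudodiffusion degrades faster than ADC at every nonzero noise level
  expect_gt(err[2, "dstar"] / err[2, "adc"], 1)
  expect_gt(err[3, "dstar"] / err[3, "adc"], 1)
})

test_that("map fitting masks invalid voxels and returns matching shapes", {
  sp <- phantom_spec(grid_shape = c(16, 16, 8), lesion_center = c(8, 8, 4),
                     lesion_radii = c(4, 4, 2), seed = 3,
                     heterogeneity = list(amplitude = 0.05))
  tr <- make_phantom(sp)
  ser <- simulate_signal(tr, default_bvalue_scheme())
  ms <- fit_map_set(ser, mask = tr$lesion_mask)
  expect_identical(dim(ms$maps$adc), dim(tr$lesion_mask))
  expect_identical(dim(ms$r2$dki), dim(tr$lesion_mask))
  expect_length(ms$maps, 6)
  # noiseless: every masked voxel fitted, none excluded
  expect_identical(ms$fit_mask, tr$lesion_mask)
  expect_false(ms$excluded)
  # the default phantom emits combined-model signals, so the pure IVIM and
  # DKI fits carry a small model mismatch but remain near-perfect
  expect_gt(unname(ms$median_r2["ivim"]), 0.999)
  expect_gt(unname(ms$median_r2["dki"]), 0.99)

  # corrupt one lesion voxel at high b: it must leave the fitted mask
  vox <- which(tr$lesion_mask, arr.ind = TRUE)[1, ]
  ser$volumes[vox[1], vox[2], vox[3], 9:11] <- 0
  ms2 <- fit_map_set(ser, mask = tr$lesion_mask)
  expect_false(ms2$fit_mask[vox[1], vox[2], vox[3]])
  expect_error(fit_map_set(ser, mask = array(FALSE, dim = dim(tr$lesion_mask))),
               "empty")
})
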