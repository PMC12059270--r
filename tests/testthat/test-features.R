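test_that("2D slice selection maximizes area with a low-index tie break", {
  # slice areas 3, 7, 7, 2: ties break to the lower index
  m2 <- array(FALSE, c(4, 4, 4))
  m2[cbind(rep(1:3, 1), 1, 1)] <- TRUE
  m2[cbind(c(1, 2, 3, 4, 1, 2, 3), c(1, 1, 1, 1, 2, 2, 2), 2)] <- TRUE
  m2[cbind(c(1, 2, 3, 4, 1, 2, 3), c(1, 1, 1, 1, 2, 2, 2), 3)] <- TRUE
  m2[cbind(1:2, 1, 4)] <- TRUE
  sel <- select_2d_slice(m2)
  expect_equal(sel$slice_index, 2L)
  expect_equal(sum(sel$mask), 7)
  # single-slice mask returns that slice
  s1 <- array(FALSE, c(3, 3, 3)); s1[2, 2, 3] <- TRUE
  expect_equal(select_2d_slice(s1)$slice_index, 3L)
  # ellipsoid: the equatorial slice wins
  sp <- phantom_spec(grid_shape = c(20, 20, 12), lesion_center = c(10, 10, 6),
                     lesion_radii = c(5, 5, 3))
  tr <- make_phantom(sp)
  expect_equal(select_2d_slice(tr$lesion_mask)$slice_index, 6L)
})

test_that("discretization follows bin-edge arithmetic and affine invariance", {
  cfg2 <- discretization_config(n_bins = 2)
  expect_equal(as.integer(discretize(c(0, 0.5, 1), cfg2)), c(1L, 2L, 2L))
  const <- discretize(rep(3.3, 5))
  expect_true(all(const == 1L))
  expect_equal(attr(const, "ng"), 1L)
  set.seed(1)
  v <- rnorm(50)
  l1 <- discretize(v, discretization_config(n_bins = 8))
  l2 <- discretize(3 + 2.5 * v, discretization_config(n_bins = 8))
  expect_identical(as.integer(l1), as.integer(l2))
  # fixed bin width
  lw <- discretize(c(0.1, 1.1, 2.9), discretization_config(
    method = "fixed_bin_width", bin_width = 1))
  expect_equal(as.integer(lw), c(1L, 2L, 3L))
})

test_that("first-order features match hand computation", {
  f <- first_order_features(c(1, 2, 3, 4))
  expect_equal(unname(f["Mean"]), 2.5)
  expect_equal(unname(f["Median"]), 2.5)
  expect_equal(unname(f["Energy"]), 30)
  expect_equal(unname(f["Range"]), 3)
  expect_equal(unname(f["RootMeanSquared"]), sqrt(30 / 4))
  expect_equal(unname(f["Variance"]), mean((c(1, 2, 3, 4) - 2.5)^2))
  expect_equal(unname(first_order_features(1:10)["10Percentile"]), 1.9)
  k <- first_order_features(rep(2, 6))
  expect_equal(unname(k["Variance"]), 0)
  expect_equal(unname(k["Range"]), 0)
  expect_equal(unname(k["Uniformity"]), 1)
  expect_equal(unname(k["Skewness"]), 0)
  expect_true(attr(k, "degenerate")["Skewness"])
  # TotalEnergy scales with the voxel volume
  fe <- first_order_features(c(1, 2), spacing = c(2, 2, 3))
  expect_equal(unname(fe["TotalEnergy"]), 12 * 5)
})

test_that("family sizes and the 93-feature manifest are exact", {
  man <- feature_manifest()
  expect_equal(nrow(man), 93)
  expect_equal(as.vector(table(factor(man$family, levels = c(
    "firstorder", "glcm", "glrlm", "glszm", "ngtdm", "gldm")))),
    c(18L, 24L, 16L, 16L, 5L, 14L))
  expect_false(any(duplicated(man$feature_id)))
})

test_that("single-direction texture examples match pair/run/zone enumeration", {
  img <- matrix(c(1, 1, 2, 2), 2, 2)  # rows: (1,2),(1,2)
  g <- glcm_features(img, ng = 2, mode = "2D",
                     directions = matrix(c(0, 1, 0), 1))
  expect_equal(unname(g["Contrast"]), 1)
  expect_equal(unname(g["JointEntropy"]), 1)
  expect_equal(unname(g["MaximumProbability"]), 0.5)

  const <- matrix(1L, 3, 3)
  gc <- glcm_features(const, ng = 1, mode = "2D")
  expect_equal(unname(gc["Contrast"]), 0)
  expect_equal(unname(gc["MaximumProbability"]), 1)

  r <- glrlm_features(matrix(c(1, 1, 2), 1, 3), ng = 2, mode = "2D",
                      directions = matrix(c(0, 1, 0), 1))
  expect_equal(unname(r["GrayLevelNonUniformity"]), 1)
  expect_equal(unname(r["RunLengthNonUniformity"]), 1)
  rl <- glrlm_features(matrix(1L, 1, 7), ng = 1, mode = "2D",
                       directions = matrix(c(0, 1, 0), 1))
  expect_equal(unname(rl["LongRunEmphasis"]), 49)
  checker <- outer(1:4, 1:4, function(i, j) ((i + j) %% 2) + 1L)
  rc <- glrlm_features(checker, ng = 2, mode = "2D",
                       directions = matrix(c(0, 1, 0), 1))
  expect_equal(unname(rc["RunLengthNonUniformity"]), 16)

  z <- glszm_features(matrix(c(1, 1, 2, 3), 2, 2), ng = 3, mode = "2D")
  expect_equal(unname(z["GrayLevelNonUniformity"]), 1)
  expect_equal(unname(z["SizeZoneNonUniformity"]), 5 / 3)
  zc <- glszm_features(matrix(2L, 3, 4), ng = 2, mode = "2D")
  expect_equal(unname(zc["ZoneEntropy"]), 0)

  nt <- ngtdm_features(matrix(1L, 3, 3), ng = 1, mode = "2D")
  expect_equal(unname(nt["Contrast"]), 0)
  expect_equal(unname(nt["Complexity"]), 0)
  expect_equal(unname(nt["Coarseness"]), 1e6)  # guard when sum(p s) = 0
  center2 <- matrix(1L, 3, 3); center2[2, 2] <- 2L
  nh <- ngtdm_features(center2, ng = 2, mode = "2D")
  s_oracle <- oracle_ngtdm(center2, "2D")
  expect_equal(as.numeric(nh), as.numeric(s_oracle), tolerance = 1e-12)

  d <- gldm_features(matrix(1L, 2, 2), ng = 1, mode = "2D")
  expect_equal(unname(d["DependenceNonUniformity"]), 4)
  expect_equal(unname(d["GrayLevelNonUniformity"]), 4)
})

test_that("every texture family matches its brute-force oracle on random volumes", {
  set.seed(7)
  for (rep in 1:8) {
    lev <- array(sample(1:4, 48, replace = TRUE), c(4, 4, 3))
    if (rep %% 2 == 0) lev[sample(48, 10)] <- 0L  # irregular ROI
    if (all(lev == 0)) next
    ng <- 4
    g <- glcm_features(lev, ng = ng, mode = "3D")
    og <- oracle_glcm(lev, "3D")
    expect_equal(unname(g[names(og)]), unname(og), tolerance = 1e-10)
    r <- glrlm_features(lev, ng = ng, mode = "3D")
    or <- oracle_glrlm(lev, "3D")
    expect_equal(unname(r[names(or)]), unname(or), tolerance = 1e-10)
    z <- glszm_features(lev, ng = ng, mode = "3D")
    oz <- oracle_glszm(lev, "3D")
    expect_equal(unname(z[names(oz)]), unname(oz), tolerance = 1e-10)
    nt <- ngtdm_features(lev, ng = ng, mode = "3D")
    on <- oracle_ngtdm(lev, "3D")
    expect_equal(unname(nt[names(on)]), unname(on), tolerance = 1e-10)
    d <- gldm_features(lev, ng = ng, mode = "3D")
    od <- oracle_gldm(lev, "3D")
    expect_equal(unname(d[names(od)]), unname(od), tolerance = 1e-10)
  }
})

test_that("in-plane rotation leaves direction-averaged 2D features unchanged", {
  set.seed(21)
  img <- matrix(sample(1:5, 36, replace = TRUE), 6, 6)
  rot <- t(img)[, 6:1]  # 90-degree rotation
  for (fn in list(glcm_features, glrlm_features, glszm_features,
                  ngtdm_features, gldm_features)) {
    a <- fn(img, ng = 5, mode = "2D")
    b <- fn(rot, ng = 5, mode = "2D")
    expect_equal(unname(a), unname(b), tolerance = 1e-10)
  }
})

test_that("map extraction yields 93 features per map, 558 per ROI mode", {
  sp <- phantom_spec(grid_shape = c(16, 16, 8), lesion_center = c(8, 8, 4),
                     lesion_radii = c(4, 4, 2), seed = 6,
                     heterogeneity = list(amplitude = 0.15, n_blobs = 15,
                                          corr_length = 2))
  tr <- make_phantom(sp)
  ser <- simulate_signal(tr, default_bvalue_scheme())
  ser <- add_rician_noise(ser, 2, seed = 5)
  ms <- fit_map_set(ser, mask = tr$lesion_mask)
  fe <- extract_features(ms, tr$lesion_mask)
  expect_equal(nrow(fe), 2 * 558)
  counts <- table(fe$roi_mode, fe$map)
  expect_true(all(counts == 93))
  expect_false(any(is.na(fe$value)))

  # single-slice lesion: first-order features agree between modes
  s1 <- array(FALSE, dim = dim(tr$lesion_mask))
  k <- select_2d_slice(tr$lesion_mask)$slice_index
  s1[, , k] <- tr$lesion_mask[, , k]
  fe1 <- extract_features(ms, s1)
  fo <- fe1[grepl("^firstorder", fe1$feature_id), ]
  w2 <- fo[fo$roi_mode == "2D", ]
  w3 <- fo[fo$roi_mode == "3D", ]
  expect_equal(w2$value, w3$value[match(paste(w2$map, w2$feature_id),
                                        paste(w3$map, w3$feature_id))])

  # affine intensity shift changes first-order Mean but no texture feature
  ms2 <- ms
  ms2$maps$adc <- ms$maps$adc + 5e-4
  fa <- extract_features(ms2, tr$lesion_mask)
  adc_a <- fa[fa$map == "adc", ]
  adc_o <- fe[fe$map == "adc", ]
  stopifnot(identical(adc_a$feature_id, adc_o$feature_id))
  tex <- !grepl("^firstorder", adc_a$feature_id)
  expect_equal(adc_a$value[tex], adc_o$value[tex], tolerance = 1e-10)
  mean_row <- adc_a$feature_id == "firstorder_Mean" & adc_a$roi_mode == "3D"
  expect_equal(adc_a$value[mean_row] - adc_o$value[mean_row], 5e-4,
               tolerance = 1e-9)
})
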