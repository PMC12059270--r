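test_that("group comparison routes by normality and matches the exact MW oracle", {
  g <- group_compare(c(1, 2, 3, 4, 5, 6), rep(c("low", "high"), each = 3),
                     method = "mann_whitney")
  expect_equal(g$p_value, 0.1)
  expect_equal(g$p_value, oracle_mw_exact(c(1, 2, 3), c(4, 5, 6)))
  set.seed(8)
  x <- rnorm(7); y <- rnorm(6) + 0.8
  g2 <- group_compare(c(x, y), rep(c("low", "high"), c(7, 6)),
                      method = "mann_whitney")
  expect_equal(g2$p_value, oracle_mw_exact(x, y), tolerance = 1e-12)
  # identical groups: no evidence of a difference
  gid <- group_compare(rep(c(1, 2, 3), 2), rep(c("low", "high"), each = 3),
                       method = "mann_whitney")
  expect_gte(gid$p_value, 0.99)
  gc <- group_compare(rep(5, 8), rep(c("low", "high"), each = 4))
  expect_equal(gc$p_value, 1)
  # clearly normal data routes to the t-test
  set.seed(9)
  xn <- rnorm(20); yn <- rnorm(20, 1)
  gt <- group_compare(c(xn, yn), rep(c("low", "high"), each = 20))
  expect_equal(gt$test_used, "t_test")
  expect_equal(gt$p_value, t.test(xn, yn, var.equal = FALSE)$p.value)
})

test_that("ICC(2,1) matches the two-way ANOVA oracle", {
  expect_equal(as.numeric(icc_two_rater(c(1, 2, 3, 4), c(1, 2, 3, 4))), 1)
  expect_equal(as.numeric(icc_two_rater(c(1, 2, 3, 4), c(2, 3, 4, 5))),
               10 / 13)
  set.seed(14)
  for (rep in 1:10) {
    a <- rnorm(12, 10, 3)
    b <- a + rnorm(12, 0.5, 1)
    expect_equal(as.numeric(icc_two_rater(a, b)), oracle_icc21(a, b),
                 tolerance = 1e-10)
  }
  # noise-dominated ratings: ICC near zero
  set.seed(15)
  vals <- replicate(20, {
    a <- rnorm(30)
    b <- a + rnorm(30, sd = 20)
    as.numeric(icc_two_rater(a, b))
  })
  expect_lt(abs(mean(vals)), 0.2)
})

test_that("AUC equals pair counting and the Mann-Whitney identity", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c("low", "low", "high", "high")), 1)
  expect_equal(roc_auc(c(0.1, 0.8, 0.2, 0.9), c("low", "low", "high", "high")), 0.75)
  expect_equal(roc_auc(rep(3, 6), rep(c("low", "high"), 3)), 0.5)
  set.seed(16)
  for (rep in 1:15) {
    sc <- rnorm(25)
    lb <- sample(c("low", "high"), 25, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(lb)) < 2) next
    expect_equal(roc_auc(sc, lb), oracle_auc(sc, lb), tolerance = 1e-12)
  }
})

null_feature_tbl <- function(n_sub, n_feat, seed, shift = 0) {
  set.seed(seed)
  stages <- rep(c("low", "high"), c(12, n_sub - 12))
  vals <- matrix(rnorm(n_sub * n_feat), n_sub)
  vals[stages == "high", ] <- vals[stages == "high", ] + shift
  list(
    features = data.frame(
      subject_id = rep(sprintf("sub%03d", 1:n_sub), n_feat),
      map = "adc", roi_mode = "3D",
      feature_id = rep(sprintf("firstorder_F%03d", 1:n_feat), each = n_sub),
      value = as.vector(vals), stringsAsFactors = FALSE),
    labels = data.frame(subject_id = sprintf("sub%03d", 1:n_sub),
                        stage = stages, stringsAsFactors = FALSE),
    vals = vals)
}

stable_records_for <- function(features) {
  u <- unique(features[, c("map", "roi_mode", "feature_id")])
  u$stable <- TRUE
  u
}

test_that("the staging screen is empty for an empty stable set and monotone", {
  nt <- null_feature_tbl(40, 10, seed = 5, shift = 1.2)
  rb <- nt$features
  rb$value <- rb$value + rnorm(nrow(rb), sd = 0.05)
  empty <- stable_records_for(nt$features)[0, ]
  expect_equal(nrow(staging_screen(nt$features, empty, rb, nt$labels)), 0)
  # enlarging the stable set never removes selected features
  full <- stable_records_for(nt$features)
  part <- full[1:4, ]
  res_part <- staging_screen(nt$features, part, rb, nt$labels)
  res_full <- staging_screen(nt$features, full, rb, nt$labels)
  sel_part <- res_part$feature_id[res_part$selected]
  sel_full <- res_full$feature_id[res_full$selected]
  expect_true(all(sel_part %in% sel_full))
})

test_that("a large stage effect is detected with high AUC and survives the gates", {
  nt <- null_feature_tbl(40, 6, seed = 11, shift = 2.5)
  rb <- nt$features
  set.seed(12)
  rb$value <- rb$value + rnorm(nrow(rb), sd = 0.1)
  res <- staging_screen(nt$features, stable_records_for(nt$features), rb,
                        nt$labels)
  expect_true(all(res$selected))
  expect_true(all(res$auc > 0.9))
  expect_true(all(res$icc > 0.75))
})

test_that("the null screen selects about alpha of stable features", {
  rates <- vapply(1:20, function(s) {
    nt <- null_feature_tbl(40, 100, seed = 100 + s, shift = 0)
    rb <- nt$features
    set.seed(200 + s)
    rb$value <- rb$value + rnorm(nrow(rb), sd = 0.05)
    res <- staging_screen(nt$features, stable_records_for(nt$features), rb,
                          nt$labels)
    mean(res$selected)
  }, 0)
  expect_equal(mean(rates), 0.05, tolerance = 0.6)  # within (0.02, 0.08)
  expect_gt(mean(rates), 0.02)
  expect_lt(mean(rates), 0.08)
})

test_that("label permutation keeps the selected count near the nominal level", {
  nt <- null_feature_tbl(40, 60, seed = 33, shift = 0)
  rb <- nt$features
  set.seed(34)
  rb$value <- rb$value + rnorm(nrow(rb), sd = 0.05)
  stable <- stable_records_for(nt$features)
  set.seed(35)
  counts <- vapply(1:30, function(p) {
    lab <- nt$labels
    lab$stage <- sample(lab$stage)
    sum(staging_screen(nt$features, stable, rb, lab)$selected)
  }, 0)
  expect_lt(abs(mean(counts) - 0.05 * 60),
            2 * sd(counts) / sqrt(length(counts)) + 1)
})
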