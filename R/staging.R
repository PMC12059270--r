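#' Normality-routed two-group comparison
#'
#' Shapiro-Wilk normality is assessed in each group at alpha = 0.05; when
#' both groups look normal a two-sided Welch t-test is used, otherwise a
#' two-sided Mann-Whitney U test (exact when min(n1, n2) <= 8 and there are
#' no ties). Constant pooled values give p = 1 with a degenerate attribute.
#'
#' @param values numeric vector
#' @param labels factor/character with levels "low" and "high" (>= 3 each)
#' @param method "auto" (the default routing), or force "t_test" /
#'   "mann_whitney"
#' @return list with `p_value` and `test_used`
#' @export
group_compare <- function(values, labels,
                          method = c("auto", "t_test", "mann_whitney")) {
  method <- match.arg(method)
  labels <- as.character(labels)
  assert_that(all(labels %in% c("low", "high")),
              "labels must be 'low' or 'high'")
  x <- values[labels == "low"]
  y <- values[labels == "high"]
  assert_that(length(x) >= 3 && length(y) >= 3,
              "need at least 3 observations per group")
  if (var(c(x, y)) == 0) {
    out <- list(p_value = 1, test_used = "degenerate")
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  normal <- function(v) {
    if (length(unique(v)) < 3) return(FALSE)
    tryCatch(shapiro.test(v)$p.value >= 0.05, error = function(e) FALSE)
  }
  use_t <- switch(method,
                  auto = normal(x) && normal(y),
                  t_test = TRUE,
                  mann_whitney = FALSE)
  if (use_t) {
    p <- t.test(x, y, var.equal = FALSE)$p.value
    list(p_value = p, test_used = "t_test")
  } else {
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- min(length(x), length(y)) <= 8 && !ties
    p <- suppressWarnings(
      wilcox.test(x, y, exact = exact, correct = !exact)$p.value)
    list(p_value = p, test_used = "mann_whitney")
  }
}

#' Two-way random-effects absolute-agreement single-measure ICC
#'
#' ICC(2,1) from the two-way ANOVA variance components:
#' (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n) with k = 2 raters.
#' Zero between-subject variance is flagged degenerate.
#'
#' @param ratings_a,ratings_b paired numeric vectors, length >= 3
#' @return ICC value in (-Inf, 1]
#' @export
icc_two_rater <- function(ratings_a, ratings_b) {
  assert_that(length(ratings_a) == length(ratings_b) &&
                length(ratings_a) >= 3,
              "ratings must be paired with length >= 3")
  n <- length(ratings_a)
  k <- 2
  m <- cbind(ratings_a, ratings_b)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom <= 0 || (msr == 0 && mse == 0 && msc == 0)) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (msr - mse) / denom
}

#' Area under the ROC curve by pair counting
#'
#' AUC = P(score_high > score_low) + P(tie)/2 with the high-stage group as
#' the positive class; no direction flipping is applied. Equivalent to the
#' Mann-Whitney U statistic divided by n1 n2.
#'
#' @param scores numeric vector
#' @param labels "low"/"high" labels, both classes present
#' @return AUC in [0, 1]
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.character(labels)
  assert_that(all(labels %in% c("low", "high")),
              "labels must be 'low' or 'high'")
  hi <- scores[labels == "high"]
  lo <- scores[labels == "low"]
  assert_that(length(hi) > 0 && length(lo) > 0, "both classes are required")
  cmp <- outer(hi, lo, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

#' Morphological perturbation of an ROI mask
#'
#' Emulates a second reader's delineation: every surface voxel (an ROI voxel
#' with an out-of-ROI face neighbor, or vice versa) is flipped with
#' probability `p_flip`, i.e. a random 1-voxel erosion/dilation pattern.
#' Deterministic given `seed`; the result is guaranteed non-empty.
#'
#' @param mask logical 3D array
#' @param seed RNG seed
#' @param p_flip per-voxel flip probability on the surface
#' @return perturbed logical 3D array
#' @export
perturb_mask <- function(mask, seed = 1L, p_flip = 0.2) {
  assert_that(any(mask), "mask is empty")
  dims <- dim(mask)
  shift <- function(m, o) {
    out <- array(FALSE, dim = dims)
    src <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
    dst <- src
    for (a in 1:3) {
      if (o[a] > 0) { dst[[a]] <- (1 + o[a]):dims[a]; src[[a]] <- 1:(dims[a] - o[a]) }
      if (o[a] < 0) { dst[[a]] <- 1:(dims[a] + o[a]); src[[a]] <- (1 - o[a]):dims[a] }
    }
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  nb <- array(FALSE, dim = dims)
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    nb <- nb | shift(mask, o)
  }
  inner_surface <- mask & !apply_all_neighbors(mask, shift)
  outer_surface <- nb & !mask
  surface <- which(inner_surface | outer_surface)
  out <- mask
  with_seed(seed, {
    flip <- surface[runif(length(surface)) < p_flip]
    out[flip] <- !out[flip]
  })
  if (!any(out)) out <- mask
  out
}

# voxels whose six face neighbors are all inside the mask
apply_all_neighbors <- function(mask, shift) {
  acc <- array(TRUE, dim = dim(mask))
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    acc <- acc & shift(mask, o)
  }
  acc
}

#' Screen stable features for association with stage
#'
#' Restricts to the stable features, runs [group_compare()] per feature,
#' gates survivors (p < `alpha`) on the two-rater ICC computed from a second
#' delineation's feature values, and computes the ROC AUC for features
#' passing the ICC gate. No multiple-testing correction is applied. Features
#' are matched between raters by (map, roi_mode, feature_id, subject).
#'
#' @param features data frame for the analysis sequence with columns
#'   `subject_id`, `map`, `roi_mode`, `feature_id`, `value`
#' @param stable_records output of [stability_table()] (or any data frame
#'   with `map`, `roi_mode`, `feature_id`, `stable`)
#' @param rater_b_features same layout as `features`, extracted from the
#'   second reader's (perturbed) masks; NULL skips the ICC gate with a
#'   warning
#' @param labels data frame with `subject_id`, `stage`
#' @param alpha significance level (default 0.05)
#' @param icc_threshold ICC gate (default 0.75)
#' @return data frame of staging records: p-value, test used, ICC, AUC and
#'   `selected` flag per stable feature
#' @export
staging_screen <- function(features, stable_records, rater_b_features,
                           labels, alpha = 0.05, icc_threshold = 0.75) {
  stable_set <- stable_records[stable_records$stable, , drop = FALSE]
  if (nrow(stable_set) == 0) {
    return(data.frame(map = character(), roi_mode = character(),
                      feature_id = character(), p_value = numeric(),
                      test_used = character(), icc = numeric(),
                      auc = numeric(), selected = logical(),
                      stringsAsFactors = FALSE))
  }
  has_b <- !is.null(rater_b_features)
  if (!has_b) {
    warning("no second-rater features: ICC gate skipped, selected undefined",
            call. = FALSE)
  }
  out <- vector("list", nrow(stable_set))
  for (r in seq_len(nrow(stable_set))) {
    rec <- stable_set[r, ]
    sel <- features$map == rec$map & features$roi_mode == rec$roi_mode &
      features$feature_id == rec$feature_id
    fa <- features[sel, ]
    fa <- fa[match(labels$subject_id, fa$subject_id), ]
    gc <- group_compare(fa$value, labels$stage)
    icc <- NA_real_
    auc <- NA_real_
    if (gc$p_value < alpha && has_b) {
      selb <- rater_b_features$map == rec$map &
        rater_b_features$roi_mode == rec$roi_mode &
        rater_b_features$feature_id == rec$feature_id
      fb <- rater_b_features[selb, ]
      fb <- fb[match(labels$subject_id, fb$subject_id), ]
      icc <- as.numeric(icc_two_rater(fa$value, fb$value))
      if (icc > icc_threshold) auc <- roc_auc(fa$value, labels$stage)
    }
    selected <- if (has_b) {
      gc$p_value < alpha && !is.na(icc) && icc > icc_threshold
    } else {
      NA
    }
    out[[r]] <- data.frame(map = rec$map, roi_mode = rec$roi_mode,
                           feature_id = rec$feature_id,
                           p_value = gc$p_value, test_used = gc$test_used,
                           icc = icc, auc = auc, selected = selected,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
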