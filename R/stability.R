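#' Lin's concordance correlation coefficient
#'
#' CCC = 2 rho sigma_x sigma_y / (sigma_x^2 + sigma_y^2 + (mu_x - mu_y)^2)
#' with population (1/n) moments (Lin's original estimator). Two identical
#' constant vectors give 1 by convention; zero variance in only one vector
#' gives 0 with a degenerate attribute.
#'
#' @param x,y paired numeric vectors (same subjects under two conditions),
#'   length >= 3
#' @return CCC in [-1, 1]
#' @export
ccc <- function(x, y) {
  assert_that(length(x) == length(y) && length(x) >= 3,
              "x and y must be paired with length >= 3")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  if (vx == 0 && vy == 0) {
    out <- if (mx == my) 1 else 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  if (vx == 0 || vy == 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  2 * cxy / (vx + vy + (mx - my)^2)
}

#' Coefficient of variation of repeated measurements
#'
#' Sample standard deviation (n - 1 denominator) divided by the absolute
#' mean. A mean within `eps` times the value scale of zero is undefined and
#' returns NA with a degenerate attribute.
#'
#' @param values one feature's values across repeated conditions (>= 2)
#' @param eps relative tolerance for a zero mean
#' @return nonnegative COV, or NA when undefined
#' @export
feature_cov <- function(values, eps = 1e-12) {
  assert_that(length(values) >= 2, "need at least 2 values")
  m <- mean(values)
  scale <- max(abs(values), na.rm = TRUE)
  if (!is.finite(m) || abs(m) < eps * max(scale, 1)) {
    out <- NA_real_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  sd(values) / abs(m)
}

#' Four-tier stability category of a CCC or COV value
#'
#' CCC: excellent (> 0.9), good (0.75, 0.9], moderate (0.5, 0.75],
#' poor (<= 0.5). COV: excellent (< 0.05), good [0.05, 0.1],
#' moderate (0.1, 0.2], poor (> 0.2). Boundaries are half-open so that the
#' stable rule (CCC > 0.9 and COV <= 0.1) aligns with the good/excellent
#' boundaries. NA maps to "undefined".
#'
#' @param value numeric value(s)
#' @param metric "ccc" or "cov"
#' @return character category vector
#' @export
categorize <- function(value, metric = c("ccc", "cov")) {
  metric <- match.arg(metric)
  out <- rep("undefined", length(value))
  ok <- is.finite(value)
  v <- value[ok]
  out[ok] <- if (metric == "ccc") {
    ifelse(v > 0.9, "excellent",
           ifelse(v > 0.75, "good",
                  ifelse(v > 0.5, "moderate", "poor")))
  } else {
    ifelse(v < 0.05, "excellent",
           ifelse(v <= 0.1, "good",
                  ifelse(v <= 0.2, "moderate", "poor")))
  }
  out
}

#' Per-feature stability across the three sequences
#'
#' For every (map, ROI mode, feature): CCC across subjects between S1 and S2
#' and between S1 and S3, and the COV across S1-S3 computed within subject
#' and then averaged over subjects with a defined value. Categories follow
#' [categorize()]; a feature is stable when COV <= 0.1 and CCC > 0.9 in both
#' pairings (`stable_rule = "both"`, the default) or in at least one
#' (`"either"`). Subjects missing a sequence are dropped per record.
#'
#' @param features data frame with columns `subject_id`, `sequence`, `map`,
#'   `roi_mode`, `feature_id`, `value`
#' @param stable_rule "both" or "either"
#' @return data frame of stability records: `map`, `roi_mode`, `feature_id`,
#'   `ccc_s1s2`, `ccc_s1s3`, `cov`, the three categories and `stable`
#' @export
stability_table <- function(features, stable_rule = c("both", "either")) {
  stable_rule <- match.arg(stable_rule)
  need <- c("subject_id", "sequence", "map", "roi_mode", "feature_id", "value")
  assert_that(all(need %in% names(features)),
              "features is missing required columns")
  key <- interaction(features$map, features$roi_mode, features$feature_id,
                     drop = TRUE, lex.order = TRUE)
  subj <- factor(features$subject_id)
  seqf <- factor(features$sequence, levels = c("S1", "S2", "S3"))
  arr <- array(NA_real_,
               dim = c(nlevels(subj), 3L, nlevels(key)),
               dimnames = list(levels(subj), levels(seqf), levels(key)))
  arr[cbind(as.integer(subj), as.integer(seqf), as.integer(key))] <-
    features$value

  meta <- unique(features[, c("map", "roi_mode", "feature_id")])
  meta_key <- interaction(meta$map, meta$roi_mode, meta$feature_id,
                          drop = TRUE, lex.order = TRUE)
  meta <- meta[match(levels(key), as.character(meta_key)), ]

  nk <- nlevels(key)
  ccc12 <- ccc13 <- covm <- rep(NA_real_, nk)
  for (j in seq_len(nk)) {
    m <- arr[, , j, drop = FALSE]
    dim(m) <- dim(arr)[1:2]
    complete <- stats::complete.cases(m)
    m <- m[complete, , drop = FALSE]
    if (nrow(m) >= 3) {
      ccc12[j] <- as.numeric(ccc(m[, 1], m[, 2]))
      ccc13[j] <- as.numeric(ccc(m[, 1], m[, 3]))
    }
    if (nrow(m) >= 1) {
      covs <- apply(m, 1, function(r) as.numeric(feature_cov(r)))
      covs <- covs[is.finite(covs)]
      if (length(covs) > 0) covm[j] <- mean(covs)
    }
  }
  min_ccc <- pmin(ccc12, ccc13)
  max_ccc <- pmax(ccc12, ccc13)
  ccc_for_rule <- if (stable_rule == "both") min_ccc else max_ccc
  stable <- !is.na(ccc_for_rule) & !is.na(covm) &
    ccc_for_rule > 0.9 & covm <= 0.1
  out <- data.frame(
    map = meta$map, roi_mode = meta$roi_mode, feature_id = meta$feature_id,
    ccc_s1s2 = ccc12, ccc_s1s3 = ccc13, cov = covm,
    ccc_s1s2_category = categorize(ccc12, "ccc"),
    ccc_s1s3_category = categorize(ccc13, "ccc"),
    cov_category = categorize(covm, "cov"),
    stable = stable, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Category and stable-feature proportion summaries
#'
#' @param records output of [stability_table()]
#' @return list of data frames: `category_overall` (category proportions per
#'   metric/comparison and ROI mode over all features), `category_by_map`
#'   (per map), `stable_by_map` (stable proportions per map and ROI mode),
#'   `stable_overall` (per ROI mode)
#' @export
summarize_stability <- function(records) {
  assert_that(nrow(records) > 0, "no stability records")
  cats <- c("poor", "moderate", "good", "excellent", "undefined")
  metrics <- c(ccc_s1s2 = "ccc_s1s2_category",
               ccc_s1s3 = "ccc_s1s3_category",
               cov = "cov_category")
  prop_tab <- function(df) {
    do.call(rbind, lapply(names(metrics), function(mt) {
      x <- factor(df[[metrics[[mt]]]], levels = cats)
      p <- as.numeric(table(x)) / nrow(df)
      data.frame(metric = mt, category = cats, proportion = p,
                 stringsAsFactors = FALSE)
    }))
  }
  category_overall <- do.call(rbind, lapply(split(records, records$roi_mode),
    function(df) cbind(roi_mode = df$roi_mode[1], prop_tab(df))))
  category_by_map <- do.call(rbind, lapply(
    split(records, list(records$roi_mode, records$map)),
    function(df) {
      if (nrow(df) == 0) return(NULL)
      cbind(roi_mode = df$roi_mode[1], map = df$map[1], prop_tab(df))
    }))
  stable_by_map <- do.call(rbind, lapply(
    split(records, list(records$roi_mode, records$map)),
    function(df) {
      if (nrow(df) == 0) return(NULL)
      data.frame(roi_mode = df$roi_mode[1], map = df$map[1],
                 n = nrow(df), stable_proportion = mean(df$stable),
                 stringsAsFactors = FALSE)
    }))
  stable_overall <- do.call(rbind, lapply(split(records, records$roi_mode),
    function(df) data.frame(roi_mode = df$roi_mode[1], n = nrow(df),
                            stable_proportion = mean(df$stable),
                            stringsAsFactors = FALSE)))
  rownames(category_overall) <- rownames(category_by_map) <-
    rownames(stable_by_map) <- rownames(stable_overall) <- NULL
  list(category_overall = category_overall,
       category_by_map = category_by_map,
       stable_by_map = stable_by_map,
       stable_overall = stable_overall)
}
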