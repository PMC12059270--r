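# Texture feature families on discretized gray-level volumes. All matrices
# use distance-1 offsets in voxels; matrices are accumulated per unique
# direction (4 in-plane for 2D, 13 for 3D) and features averaged over
# directions with at least one entry. Zone/dependence families use the full
# neighborhood (8-connectivity in 2D, 26 in 3D). Degenerate inputs (e.g. a
# single-voxel ROI) return 0 for every feature with a degenerate flag.

GLCM_NAMES <- c(
  "Autocorrelation", "JointAverage", "ClusterProminence", "ClusterShade",
  "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
  "DifferenceEntropy", "DifferenceVariance", "JointEnergy", "JointEntropy",
  "Imc1", "Imc2", "Idm", "Idmn", "Id", "Idn", "InverseVariance",
  "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares", "MCC"
)
GLRLM_NAMES <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
  "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
  "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
  "ShortRunLowGrayLevelEmphasis"
)
GLSZM_NAMES <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
  "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "ZoneEntropy", "ZonePercentage", "ZoneVariance"
)
NGTDM_NAMES <- c("Coarseness", "Contrast", "Busyness", "Complexity",
                 "Strength")
GLDM_NAMES <- c(
  "DependenceEntropy", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "DependenceVariance",
  "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
  "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
  "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
  "SmallDependenceLowGrayLevelEmphasis"
)

EPS_GUARD <- 1e-6  # guard for undefined ratio features

# Maximal correlation coefficient of a normalized symmetric GLCM: sqrt of the
# second-largest eigenvalue of Q(i,j) = sum_k P(i,k)P(j,k)/(px(i)px(k)) over
# non-empty gray levels; degenerates to 1 with fewer than two levels present.
glcm_mcc <- function(P) {
  px <- rowSums(P)
  keep <- which(px > 0)
  m <- length(keep)
  if (m <= 1) return(1)
  Pk <- P[keep, keep, drop = FALSE]
  pk <- px[keep]
  A <- Pk / pk                      # rows scaled by px(i)
  B <- Pk %*% diag(1 / pk, m)       # columns scaled by px(k)
  ev <- sort(Re(eigen(A %*% t(B), only.values = TRUE)$values),
             decreasing = TRUE)
  sqrt(min(max(ev[2], 0), 1))
}

#' Unique texture directions at distance 1
#'
#' @param mode "2D" (4 in-plane directions) or "3D" (13 unique directions)
#' @return integer matrix of voxel offsets, one direction per row
#' @noRd
texture_directions <- function(mode) {
  if (mode == "2D") {
    matrix(c(1, 0, 0,
             0, 1, 0,
             1, 1, 0,
             1, -1, 0), ncol = 3, byrow = TRUE)
  } else {
    matrix(c(1, 0, 0,  0, 1, 0,  0, 0, 1,
             1, 1, 0,  1, -1, 0,  1, 0, 1,
             1, 0, -1,  0, 1, 1,  0, 1, -1,
             1, 1, 1,  1, 1, -1,  1, -1, 1,
             1, -1, -1), ncol = 3, byrow = TRUE)
  }
}

full_neighborhood <- function(mode) {
  d <- texture_directions(mode)
  rbind(d, -d)
}

# coerce to a 3D integer array with 0 outside the ROI
as_level_array <- function(levels) {
  if (is.null(dim(levels))) stop("levels must be an array", call. = FALSE)
  if (length(dim(levels)) == 2L) dim(levels) <- c(dim(levels), 1L)
  lev <- as.integer(levels)
  lev[is.na(lev)] <- 0L
  dim(lev) <- dim(levels)
  lev
}

degenerate_family <- function(names) {
  out <- setNames(rep(0, length(names)), names)
  attr(out, "degenerate") <- setNames(rep(TRUE, length(names)), names)
  out
}

finish_family <- function(values, names) {
  out <- setNames(values, names)
  attr(out, "degenerate") <- setNames(rep(FALSE, length(names)), names)
  out
}

entropy2 <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0) return(0)
  -sum(p * log2(p))
}

# ---- GLCM --------------------------------------------------------------

glcm_features_one <- function(P, ng) {
  iv <- seq_len(ng)
  I <- matrix(iv, ng, ng)
  J <- t(I)
  px <- rowSums(P)  # symmetric: px == py
  ux <- sum(iv * px)
  sigx2 <- sum((iv - ux)^2 * px)

  sum_groups <- as.vector(I + J)
  diff_groups <- as.vector(abs(I - J))
  ps <- numeric(2 * ng)
  tmp <- rowsum(as.vector(P), group = sum_groups)
  ps[as.integer(rownames(tmp))] <- tmp
  pd <- numeric(ng)
  tmp <- rowsum(as.vector(P), group = diff_groups)
  pd[as.integer(rownames(tmp)) + 1L] <- tmp
  ks <- seq_len(2 * ng)
  kd <- 0:(ng - 1)

  HXY <- entropy2(P)
  HX <- entropy2(px)
  pxy <- outer(px, px)
  pos <- P > 0 & pxy > 0
  HXY1 <- -sum(P[pos] * log2(pxy[pos]))
  HXY2 <- entropy2(pxy)

  da <- sum(kd * pd)
  contrast <- sum((I - J)^2 * P)
  autoc <- sum(I * J * P)
  offd <- I != J

  c(
    Autocorrelation = autoc,
    JointAverage = ux,
    ClusterProminence = sum((I + J - 2 * ux)^4 * P),
    ClusterShade = sum((I + J - 2 * ux)^3 * P),
    ClusterTendency = sum((I + J - 2 * ux)^2 * P),
    Contrast = contrast,
    Correlation = if (sigx2 > 0) (autoc - ux^2) / sigx2 else 1,
    DifferenceAverage = da,
    DifferenceEntropy = entropy2(pd),
    DifferenceVariance = sum((kd - da)^2 * pd),
    JointEnergy = sum(P^2),
    JointEntropy = HXY,
    Imc1 = if (HX > 0) (HXY - HXY1) / HX else 0,
    Imc2 = if (HXY2 >= HXY) sqrt(1 - exp(-2 * (HXY2 - HXY))) else 0,
    Idm = sum(P / (1 + (I - J)^2)),
    Idmn = sum(P / (1 + ((I - J) / ng)^2)),
    Id = sum(P / (1 + abs(I - J))),
    Idn = sum(P / (1 + abs(I - J) / ng)),
    InverseVariance = sum(P[offd] / (I[offd] - J[offd])^2),
    MaximumProbability = max(P),
    SumAverage = sum(ks * ps),
    SumEntropy = entropy2(ps),
    SumSquares = sum((I - ux)^2 * P),
    MCC = glcm_mcc(P)
  )
}

#' Gray-level co-occurrence matrix features
#'
#' Symmetric co-occurrence matrices at distance 1 are built per direction,
#' normalized, and the 24 standard features are averaged over directions
#' with at least one voxel pair.
#'
#' @param levels integer gray-level array (1..Ng inside the ROI, 0 or NA
#'   outside); a matrix is treated as a single slice
#' @param ng number of gray levels (default: max level present)
#' @param mode "2D" or "3D" direction set
#' @param directions optional offset matrix overriding the mode's default
#' @return named numeric vector of 24 features with a `degenerate` attribute
#' @export
glcm_features <- function(levels, ng = NULL, mode = c("3D", "2D"),
                          directions = NULL) {
  mode <- match.arg(mode)
  lev <- as_level_array(levels)
  ng <- ng %||% max(lev)
  if (ng < 1) return(degenerate_family(GLCM_NAMES))
  offs <- directions %||% texture_directions(mode)
  counts <- glcm_counts_cpp(as.vector(lev), dim(lev), ng,
                            matrix(as.integer(offs), ncol = 3))
  nd <- dim(counts)[3]
  acc <- NULL
  used <- 0L
  for (d in seq_len(nd)) {
    M <- matrix(counts[, , d], ng, ng)
    tot <- sum(M)
    if (tot == 0) next
    fv <- glcm_features_one(M / tot, ng)
    acc <- if (is.null(acc)) fv else acc + fv
    used <- used + 1L
  }
  if (used == 0L) return(degenerate_family(GLCM_NAMES))
  finish_family(acc / used, GLCM_NAMES)
}

# ---- GLRLM -------------------------------------------------------------

glrlm_features_one <- function(cnt, ng, maxlen, np) {
  nr <- sum(cnt)
  pr <- cnt / nr
  iv <- seq_len(ng)
  jv <- seq_len(maxlen)
  wi <- matrix(iv, ng, maxlen)
  wj <- matrix(jv, ng, maxlen, byrow = TRUE)
  ri <- rowSums(cnt)
  rj <- colSums(cnt)
  pi_ <- rowSums(pr)
  pj_ <- colSums(pr)
  mu_i <- sum(iv * pi_)
  mu_j <- sum(jv * pj_)
  c(
    GrayLevelNonUniformity = sum(ri^2) / nr,
    GrayLevelNonUniformityNormalized = sum(ri^2) / nr^2,
    GrayLevelVariance = sum((wi - mu_i)^2 * pr),
    HighGrayLevelRunEmphasis = sum(wi^2 * pr),
    LongRunEmphasis = sum(wj^2 * pr),
    LongRunHighGrayLevelEmphasis = sum(wi^2 * wj^2 * pr),
    LongRunLowGrayLevelEmphasis = sum(wj^2 / wi^2 * pr),
    LowGrayLevelRunEmphasis = sum(pr / wi^2),
    RunEntropy = entropy2(pr),
    RunLengthNonUniformity = sum(rj^2) / nr,
    RunLengthNonUniformityNormalized = sum(rj^2) / nr^2,
    RunPercentage = nr / np,
    RunVariance = sum((wj - mu_j)^2 * pr),
    ShortRunEmphasis = sum(pr / wj^2),
    ShortRunHighGrayLevelEmphasis = sum(wi^2 / wj^2 * pr),
    ShortRunLowGrayLevelEmphasis = sum(pr / (wi^2 * wj^2))
  )
}

#' Gray-level run-length matrix features
#'
#' Run-length matrices per direction (runs of equal-level in-ROI voxels),
#' features averaged over directions.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 16 features with a `degenerate` attribute
#' @export
glrlm_features <- function(levels, ng = NULL, mode = c("3D", "2D"),
                           directions = NULL) {
  mode <- match.arg(mode)
  lev <- as_level_array(levels)
  ng <- ng %||% max(lev)
  if (ng < 1) return(degenerate_family(GLRLM_NAMES))
  np <- sum(lev > 0)
  offs <- directions %||% texture_directions(mode)
  runs <- glrlm_runs_cpp(as.vector(lev), dim(lev),
                         matrix(as.integer(offs), ncol = 3))
  if (length(runs$dir) == 0) return(degenerate_family(GLRLM_NAMES))
  maxlen <- max(runs$length)
  nd <- max(runs$dir)
  acc <- NULL
  used <- 0L
  for (d in seq_len(nd)) {
    sel <- runs$dir == d
    if (!any(sel)) next
    cnt <- matrix(0, ng, maxlen)
    idx <- (runs$length[sel] - 1L) * ng + runs$level[sel]
    tab <- tabulate(idx, nbins = ng * maxlen)
    cnt[] <- tab
    fv <- glrlm_features_one(cnt, ng, maxlen, np)
    acc <- if (is.null(acc)) fv else acc + fv
    used <- used + 1L
  }
  finish_family(acc / used, GLRLM_NAMES)
}

# ---- GLSZM -------------------------------------------------------------

#' Gray-level size-zone matrix features
#'
#' Connected zones of equal gray level (8-connectivity in 2D, 26 in 3D); a
#' single matrix per ROI, 16 standard features.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 16 features with a `degenerate` attribute
#' @export
glszm_features <- function(levels, ng = NULL, mode = c("3D", "2D"),
                           directions = NULL) {
  mode <- match.arg(mode)
  lev <- as_level_array(levels)
  ng <- ng %||% max(lev)
  if (ng < 1) return(degenerate_family(GLSZM_NAMES))
  np <- sum(lev > 0)
  offs <- directions %||% full_neighborhood(mode)
  zones <- glszm_zones_cpp(as.vector(lev), dim(lev),
                           matrix(as.integer(offs), ncol = 3))
  nz <- length(zones$level)
  if (nz == 0) return(degenerate_family(GLSZM_NAMES))
  maxsize <- max(zones$size)
  cnt <- matrix(0, ng, maxsize)
  idx <- (zones$size - 1L) * ng + zones$level
  cnt[] <- tabulate(idx, nbins = ng * maxsize)
  pz <- cnt / nz
  iv <- seq_len(ng)
  jv <- seq_len(maxsize)
  wi <- matrix(iv, ng, maxsize)
  wj <- matrix(jv, ng, maxsize, byrow = TRUE)
  zi <- rowSums(cnt)
  zj <- colSums(cnt)
  mu_i <- sum(iv * rowSums(pz))
  mu_j <- sum(jv * colSums(pz))
  finish_family(c(
    GrayLevelNonUniformity = sum(zi^2) / nz,
    GrayLevelNonUniformityNormalized = sum(zi^2) / nz^2,
    GrayLevelVariance = sum((wi - mu_i)^2 * pz),
    HighGrayLevelZoneEmphasis = sum(wi^2 * pz),
    LargeAreaEmphasis = sum(wj^2 * pz),
    LargeAreaHighGrayLevelEmphasis = sum(wi^2 * wj^2 * pz),
    LargeAreaLowGrayLevelEmphasis = sum(wj^2 / wi^2 * pz),
    LowGrayLevelZoneEmphasis = sum(pz / wi^2),
    SizeZoneNonUniformity = sum(zj^2) / nz,
    SizeZoneNonUniformityNormalized = sum(zj^2) / nz^2,
    SmallAreaEmphasis = sum(pz / wj^2),
    SmallAreaHighGrayLevelEmphasis = sum(wi^2 / wj^2 * pz),
    SmallAreaLowGrayLevelEmphasis = sum(pz / (wi^2 * wj^2)),
    ZoneEntropy = entropy2(pz),
    ZonePercentage = nz / np,
    ZoneVariance = sum((wj - mu_j)^2 * pz)
  ), GLSZM_NAMES)
}

# ---- NGTDM -------------------------------------------------------------

#' Neighborhood gray-tone difference features
#'
#' Coarseness, Contrast, Busyness, Complexity and Strength from the
#' neighborhood-average absolute gray-tone differences (distance-1 full
#' neighborhood, in-ROI neighbors only).
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 5 features with a `degenerate` attribute
#' @export
ngtdm_features <- function(levels, ng = NULL, mode = c("3D", "2D"),
                           directions = NULL) {
  mode <- match.arg(mode)
  lev <- as_level_array(levels)
  ng <- ng %||% max(lev)
  if (ng < 1) return(degenerate_family(NGTDM_NAMES))
  offs <- directions %||% full_neighborhood(mode)
  cs <- ngtdm_counts_cpp(as.vector(lev), dim(lev), ng,
                         matrix(as.integer(offs), ncol = 3))
  nvec <- cs$n
  svec <- cs$s
  N <- sum(nvec)
  if (N <= 1) return(degenerate_family(NGTDM_NAMES))
  p <- nvec / N
  present <- which(p > 0)
  ngp <- length(present)
  iv <- seq_len(ng)
  ps <- sum(p * svec)
  coarseness <- if (ps > 0) 1 / ps else 1 / EPS_GUARD
  if (ngp > 1) {
    ii <- matrix(iv[present], ngp, ngp)
    jj <- t(ii)
    pi_ <- matrix(p[present], ngp, ngp)
    pj_ <- t(pi_)
    si_ <- matrix(svec[present], ngp, ngp)
    sj_ <- t(si_)
    contrast <- sum(pi_ * pj_ * (ii - jj)^2) / (ngp * (ngp - 1)) *
      sum(svec) / N
    denom_b <- sum(abs(ii * pi_ - jj * pj_))
    busyness <- if (denom_b > 0) ps / denom_b else 0
    complexity <- sum(abs(ii - jj) * (pi_ * si_ + pj_ * sj_) /
                        (pi_ + pj_)) / N
    ssum <- sum(svec)
    strength <- if (ssum > 0) sum((pi_ + pj_) * (ii - jj)^2) / ssum else 0
  } else {
    contrast <- 0
    busyness <- 0
    complexity <- 0
    strength <- 0
  }
  finish_family(c(Coarseness = coarseness, Contrast = contrast,
                  Busyness = busyness, Complexity = complexity,
                  Strength = strength), NGTDM_NAMES)
}

# ---- GLDM --------------------------------------------------------------

#' Gray-level dependence matrix features
#'
#' The dependence of a voxel is the number of distance-1 in-ROI neighbors
#' whose gray level differs from the center by at most `alpha`. The
#' dependence matrix counts (level, dependence) pairs over all ROI voxels;
#' size-weighted features use j = dependence + 1 (the center voxel counts
#' itself), so that a voxel with no qualifying neighbors has size 1.
#'
#' @inheritParams glcm_features
#' @param alpha gray-level difference tolerance (default 0)
#' @return named numeric vector of 14 features with a `degenerate` attribute
#' @export
gldm_features <- function(levels, ng = NULL, mode = c("3D", "2D"),
                          alpha = 0, directions = NULL) {
  mode <- match.arg(mode)
  lev <- as_level_array(levels)
  ng <- ng %||% max(lev)
  if (ng < 1) return(degenerate_family(GLDM_NAMES))
  offs <- directions %||% full_neighborhood(mode)
  pairs <- gldm_pairs_cpp(as.vector(lev), dim(lev),
                          matrix(as.integer(offs), ncol = 3),
                          as.integer(alpha))
  nzv <- nrow(pairs)
  if (nzv <= 1) return(degenerate_family(GLDM_NAMES))
  dep <- pairs[, 2] + 1L  # j = dependence + 1
  maxj <- max(dep)
  cnt <- matrix(0, ng, maxj)
  idx <- (dep - 1L) * ng + pairs[, 1]
  cnt[] <- tabulate(idx, nbins = ng * maxj)
  pz <- cnt / nzv
  iv <- seq_len(ng)
  jv <- seq_len(maxj)
  wi <- matrix(iv, ng, maxj)
  wj <- matrix(jv, ng, maxj, byrow = TRUE)
  di <- rowSums(cnt)
  dj <- colSums(cnt)
  mu_i <- sum(iv * rowSums(pz))
  mu_j <- sum(jv * colSums(pz))
  finish_family(c(
    DependenceEntropy = entropy2(pz),
    DependenceNonUniformity = sum(dj^2) / nzv,
    DependenceNonUniformityNormalized = sum(dj^2) / nzv^2,
    DependenceVariance = sum((wj - mu_j)^2 * pz),
    GrayLevelNonUniformity = sum(di^2) / nzv,
    GrayLevelVariance = sum((wi - mu_i)^2 * pz),
    HighGrayLevelEmphasis = sum(wi^2 * pz),
    LargeDependenceEmphasis = sum(wj^2 * pz),
    LargeDependenceHighGrayLevelEmphasis = sum(wi^2 * wj^2 * pz),
    LargeDependenceLowGrayLevelEmphasis = sum(wj^2 / wi^2 * pz),
    LowGrayLevelEmphasis = sum(pz / wi^2),
    SmallDependenceEmphasis = sum(pz / wj^2),
    SmallDependenceHighGrayLevelEmphasis = sum(wi^2 / wj^2 * pz),
    SmallDependenceLowGrayLevelEmphasis = sum(pz / (wi^2 * wj^2))
  ), GLDM_NAMES)
}
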