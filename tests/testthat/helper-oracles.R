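# Independent brute-force oracles, written naively (explicit loops, direct
# formula transcription) so they share no code with the package internals.

oracle_dirs_2d <- list(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, -1, 0))
oracle_dirs_3d <- list(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0), c(1, -1, 0), c(1, 0, 1),
  c(1, 0, -1), c(0, 1, 1), c(0, 1, -1), c(1, 1, 1), c(1, 1, -1),
  c(1, -1, 1), c(1, -1, -1))
oracle_neigh <- function(dirs) c(dirs, lapply(dirs, function(d) -d))

oracle_entropy <- function(p) {
  s <- 0
  for (v in p) if (v > 0) s <- s - v * log2(v)
  s
}

as3d <- function(a) { if (length(dim(a)) == 2) dim(a) <- c(dim(a), 1); a }

# ---- GLCM ---------------------------------------------------------------

oracle_glcm_matrix <- function(lev, off) {
  lev <- as3d(lev)
  ng <- max(lev)
  P <- matrix(0, ng, ng)
  dims <- dim(lev)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    i <- lev[x, y, z]
    if (i == 0) next
    q <- c(x, y, z) + off
    if (any(q < 1) || any(q > dims)) next
    j <- lev[q[1], q[2], q[3]]
    if (j == 0) next
    P[i, j] <- P[i, j] + 1
    P[j, i] <- P[j, i] + 1
  }
  P
}

oracle_glcm_one <- function(P) {
  ng <- nrow(P)
  P <- P / sum(P)
  px <- rowSums(P)
  mu <- 0
  for (i in 1:ng) mu <- mu + i * px[i]
  sig2 <- 0
  for (i in 1:ng) sig2 <- sig2 + (i - mu)^2 * px[i]
  ps <- rep(0, 2 * ng); pd <- rep(0, ng)
  for (i in 1:ng) for (j in 1:ng) {
    ps[i + j] <- ps[i + j] + P[i, j]
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
  }
  f <- c()
  f["Autocorrelation"] <- sum(sapply(1:ng, function(i)
    sum(sapply(1:ng, function(j) i * j * P[i, j]))))
  f["JointAverage"] <- mu
  for (nm in c("ClusterProminence", "ClusterShade", "ClusterTendency")) {
    pw <- c(ClusterProminence = 4, ClusterShade = 3, ClusterTendency = 2)[[nm]]
    acc <- 0
    for (i in 1:ng) for (j in 1:ng) acc <- acc + (i + j - 2 * mu)^pw * P[i, j]
    f[nm] <- acc
  }
  acc <- 0
  for (i in 1:ng) for (j in 1:ng) acc <- acc + (i - j)^2 * P[i, j]
  f["Contrast"] <- acc
  f["Correlation"] <- if (sig2 > 0) (f[["Autocorrelation"]] - mu^2) / sig2 else 1
  da <- 0
  for (k in 0:(ng - 1)) da <- da + k * pd[k + 1]
  f["DifferenceAverage"] <- da
  f["DifferenceEntropy"] <- oracle_entropy(pd)
  dv <- 0
  for (k in 0:(ng - 1)) dv <- dv + (k - da)^2 * pd[k + 1]
  f["DifferenceVariance"] <- dv
  f["JointEnergy"] <- sum(P^2)
  hxy <- oracle_entropy(as.vector(P))
  f["JointEntropy"] <- hxy
  hx <- oracle_entropy(px)
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    pp <- px[i] * px[j]
    if (pp > 0) {
      if (P[i, j] > 0) hxy1 <- hxy1 - P[i, j] * log2(pp)
      hxy2 <- hxy2 - pp * log2(pp)
    }
  }
  f["Imc1"] <- if (hx > 0) (hxy - hxy1) / hx else 0
  f["Imc2"] <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0
  idm <- idmn <- id <- idn <- iv <- 0
  for (i in 1:ng) for (j in 1:ng) {
    idm <- idm + P[i, j] / (1 + (i - j)^2)
    idmn <- idmn + P[i, j] / (1 + ((i - j) / ng)^2)
    id <- id + P[i, j] / (1 + abs(i - j))
    idn <- idn + P[i, j] / (1 + abs(i - j) / ng)
    if (i != j) iv <- iv + P[i, j] / (i - j)^2
  }
  f["Idm"] <- idm; f["Idmn"] <- idmn; f["Id"] <- id; f["Idn"] <- idn
  f["InverseVariance"] <- iv
  f["MaximumProbability"] <- max(P)
  sa <- 0
  for (k in 2:(2 * ng)) sa <- sa + k * ps[k]
  f["SumAverage"] <- sa
  f["SumEntropy"] <- oracle_entropy(ps)
  ss <- 0
  for (i in 1:ng) for (j in 1:ng) ss <- ss + (i - mu)^2 * P[i, j]
  f["SumSquares"] <- ss
  keep <- which(px > 0)
  if (length(keep) <= 1) {
    f["MCC"] <- 1
  } else {
    m <- length(keep)
    Q <- matrix(0, m, m)
    for (a in 1:m) for (b in 1:m) {
      acc <- 0
      for (cc in 1:m) {
        ia <- keep[a]; ib <- keep[b]; ik <- keep[cc]
        acc <- acc + P[ia, ik] * P[ib, ik] / (px[ia] * px[ik])
      }
      Q[a, b] <- acc
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    f["MCC"] <- sqrt(min(max(ev[2], 0), 1))
  }
  f
}

oracle_glcm <- function(lev, mode = "3D") {
  lev <- as3d(lev)
  dirs <- if (mode == "2D") oracle_dirs_2d else oracle_dirs_3d
  acc <- NULL; used <- 0
  for (d in dirs) {
    P <- oracle_glcm_matrix(lev, d)
    if (sum(P) == 0) next
    fv <- oracle_glcm_one(P)
    acc <- if (is.null(acc)) fv else acc + fv
    used <- used + 1
  }
  acc / used
}

# ---- GLRLM --------------------------------------------------------------

oracle_glrlm_matrix <- function(lev, off) {
  lev <- as3d(lev)
  ng <- max(lev)
  dims <- dim(lev)
  runs <- list()
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    i <- lev[x, y, z]
    if (i == 0) next
    p <- c(x, y, z) - off
    if (!(any(p < 1) || any(p > dims)) && lev[p[1], p[2], p[3]] == i) next
    len <- 1
    q <- c(x, y, z) + off
    while (!(any(q < 1) || any(q > dims)) && lev[q[1], q[2], q[3]] == i) {
      len <- len + 1
      q <- q + off
    }
    runs[[length(runs) + 1]] <- c(i, len)
  }
  if (length(runs) == 0) return(NULL)
  maxlen <- max(sapply(runs, `[`, 2))
  R <- matrix(0, ng, maxlen)
  for (r in runs) R[r[1], r[2]] <- R[r[1], r[2]] + 1
  R
}

oracle_sizezone_features <- function(R, np, style) {
  # shared naive formulas for run/zone/dependence style matrices
  ng <- nrow(R); mx <- ncol(R)
  nr <- sum(R)
  p <- R / nr
  ri <- rowSums(R); rj <- colSums(R)
  mu_i <- 0; mu_j <- 0
  for (i in 1:ng) for (j in 1:mx) {
    mu_i <- mu_i + i * p[i, j]
    mu_j <- mu_j + j * p[i, j]
  }
  acc <- function(w) {
    s <- 0
    for (i in 1:ng) for (j in 1:mx) s <- s + w(i, j) * p[i, j]
    s
  }
  f <- c(
    GLN = sum(ri^2) / nr, GLNN = sum(ri^2) / nr^2,
    GLV = acc(function(i, j) (i - mu_i)^2),
    HGL = acc(function(i, j) i^2),
    Long = acc(function(i, j) j^2),
    LongHigh = acc(function(i, j) i^2 * j^2),
    LongLow = acc(function(i, j) j^2 / i^2),
    LGL = acc(function(i, j) 1 / i^2),
    Entropy = oracle_entropy(as.vector(p)),
    RLN = sum(rj^2) / nr, RLNN = sum(rj^2) / nr^2,
    Percentage = nr / np,
    RV = acc(function(i, j) (j - mu_j)^2),
    Short = acc(function(i, j) 1 / j^2),
    ShortHigh = acc(function(i, j) i^2 / j^2),
    ShortLow = acc(function(i, j) 1 / (i^2 * j^2))
  )
  f
}

oracle_glrlm <- function(lev, mode = "3D") {
  lev <- as3d(lev)
  np <- sum(lev > 0)
  dirs <- if (mode == "2D") oracle_dirs_2d else oracle_dirs_3d
  acc <- NULL; used <- 0
  for (d in dirs) {
    R <- oracle_glrlm_matrix(lev, d)
    if (is.null(R)) next
    fv <- oracle_sizezone_features(R, np, "rl")
    acc <- if (is.null(acc)) fv else acc + fv
    used <- used + 1
  }
  out <- acc / used
  names(out) <- c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                  "GrayLevelVariance", "HighGrayLevelRunEmphasis",
                  "LongRunEmphasis", "LongRunHighGrayLevelEmphasis",
                  "LongRunLowGrayLevelEmphasis", "LowGrayLevelRunEmphasis",
                  "RunEntropy", "RunLengthNonUniformity",
                  "RunLengthNonUniformityNormalized", "RunPercentage",
                  "RunVariance", "ShortRunEmphasis",
                  "ShortRunHighGrayLevelEmphasis",
                  "ShortRunLowGrayLevelEmphasis")
  out
}

# ---- GLSZM --------------------------------------------------------------

oracle_glszm_zones <- function(lev, mode = "3D") {
  lev <- as3d(lev)
  dims <- dim(lev)
  neigh <- oracle_neigh(if (mode == "2D") oracle_dirs_2d else oracle_dirs_3d)
  seen <- array(FALSE, dim = dims)
  zones <- list()
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (seen[x, y, z] || lev[x, y, z] == 0) next
    g <- lev[x, y, z]
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (o in neigh) {
        q <- v + o
        if (any(q < 1) || any(q > dims)) next
        if (!seen[q[1], q[2], q[3]] && lev[q[1], q[2], q[3]] == g) {
          seen[q[1], q[2], q[3]] <- TRUE
          queue[[length(queue) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <- c(g, size)
  }
  zones
}

oracle_glszm <- function(lev, mode = "3D") {
  lev <- as3d(lev)
  np <- sum(lev > 0)
  zones <- oracle_glszm_zones(lev, mode)
  ng <- max(lev)
  mx <- max(sapply(zones, `[`, 2))
  Z <- matrix(0, ng, mx)
  for (zn in zones) Z[zn[1], zn[2]] <- Z[zn[1], zn[2]] + 1
  nz <- sum(Z)
  p <- Z / nz
  zi <- rowSums(Z); zj <- colSums(Z)
  mu_i <- 0; mu_j <- 0
  for (i in 1:ng) for (j in 1:mx) {
    mu_i <- mu_i + i * p[i, j]; mu_j <- mu_j + j * p[i, j]
  }
  acc <- function(w) {
    s <- 0
    for (i in 1:ng) for (j in 1:mx) s <- s + w(i, j) * p[i, j]
    s
  }
  c(GrayLevelNonUniformity = sum(zi^2) / nz,
    GrayLevelNonUniformityNormalized = sum(zi^2) / nz^2,
    GrayLevelVariance = acc(function(i, j) (i - mu_i)^2),
    HighGrayLevelZoneEmphasis = acc(function(i, j) i^2),
    LargeAreaEmphasis = acc(function(i, j) j^2),
    LargeAreaHighGrayLevelEmphasis = acc(function(i, j) i^2 * j^2),
    LargeAreaLowGrayLevelEmphasis = acc(function(i, j) j^2 / i^2),
    LowGrayLevelZoneEmphasis = acc(function(i, j) 1 / i^2),
    SizeZoneNonUniformity = sum(zj^2) / nz,
    SizeZoneNonUniformityNormalized = sum(zj^2) / nz^2,
    SmallAreaEmphasis = acc(function(i, j) 1 / j^2),
    SmallAreaHighGrayLevelEmphasis = acc(function(i, j) i^2 / j^2),
    SmallAreaLowGrayLevelEmphasis = acc(function(i, j) 1 / (i^2 * j^2)),
    ZoneEntropy = oracle_entropy(as.vector(p)),
    ZonePercentage = nz / np,
    ZoneVariance = acc(function(i, j) (j - mu_j)^2))
}

# ---- NGTDM --------------------------------------------------------------

oracle_ngtdm <- function(lev, mode = "3D") {
  lev <- as3d(lev)
  dims <- dim(lev)
  neigh <- oracle_neigh(if (mode == "2D") oracle_dirs_2d else oracle_dirs_3d)
  ng <- max(lev)
  nvec <- rep(0, ng); svec <- rep(0, ng)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    i <- lev[x, y, z]
    if (i == 0) next
    vals <- c()
    for (o in neigh) {
      q <- c(x, y, z) + o
      if (any(q < 1) || any(q > dims)) next
      lj <- lev[q[1], q[2], q[3]]
      if (lj > 0) vals <- c(vals, lj)
    }
    nvec[i] <- nvec[i] + 1
    if (length(vals) > 0) svec[i] <- svec[i] + abs(i - mean(vals))
  }
  N <- sum(nvec)
  p <- nvec / N
  pres <- which(p > 0)
  ngp <- length(pres)
  ps <- sum(p * svec)
  coars <- if (ps > 0) 1 / ps else 1e6
  if (ngp <= 1) {
    return(c(Coarseness = coars, Contrast = 0, Busyness = 0, Complexity = 0,
             Strength = 0))
  }
  contr <- 0; den_b <- 0; compl <- 0; stren <- 0
  for (i in pres) for (j in pres) {
    contr <- contr + p[i] * p[j] * (i - j)^2
    den_b <- den_b + abs(i * p[i] - j * p[j])
    compl <- compl + abs(i - j) * (p[i] * svec[i] + p[j] * svec[j]) /
      (p[i] + p[j])
    stren <- stren + (p[i] + p[j]) * (i - j)^2
  }
  c(Coarseness = coars,
    Contrast = contr / (ngp * (ngp - 1)) * sum(svec) / N,
    Busyness = if (den_b > 0) ps / den_b else 0,
    Complexity = compl / N,
    Strength = if (sum(svec) > 0) stren / sum(svec) else 0)
}

# ---- GLDM ---------------------------------------------------------------

oracle_gldm <- function(lev, mode = "3D", alpha = 0) {
  lev <- as3d(lev)
  dims <- dim(lev)
  neigh <- oracle_neigh(if (mode == "2D") oracle_dirs_2d else oracle_dirs_3d)
  recs <- list()
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    i <- lev[x, y, z]
    if (i == 0) next
    dep <- 0
    for (o in neigh) {
      q <- c(x, y, z) + o
      if (any(q < 1) || any(q > dims)) next
      lj <- lev[q[1], q[2], q[3]]
      if (lj > 0 && abs(lj - i) <= alpha) dep <- dep + 1
    }
    recs[[length(recs) + 1]] <- c(i, dep + 1)
  }
  ng <- max(lev)
  mx <- max(sapply(recs, `[`, 2))
  D <- matrix(0, ng, mx)
  for (r in recs) D[r[1], r[2]] <- D[r[1], r[2]] + 1
  nz <- sum(D)
  p <- D / nz
  di <- rowSums(D); dj <- colSums(D)
  mu_i <- 0; mu_j <- 0
  for (i in 1:ng) for (j in 1:mx) {
    mu_i <- mu_i + i * p[i, j]; mu_j <- mu_j + j * p[i, j]
  }
  acc <- function(w) {
    s <- 0
    for (i in 1:ng) for (j in 1:mx) s <- s + w(i, j) * p[i, j]
    s
  }
  c(DependenceEntropy = oracle_entropy(as.vector(p)),
    DependenceNonUniformity = sum(dj^2) / nz,
    DependenceNonUniformityNormalized = sum(dj^2) / nz^2,
    DependenceVariance = acc(function(i, j) (j - mu_j)^2),
    GrayLevelNonUniformity = sum(di^2) / nz,
    GrayLevelVariance = acc(function(i, j) (i - mu_i)^2),
    HighGrayLevelEmphasis = acc(function(i, j) i^2),
    LargeDependenceEmphasis = acc(function(i, j) j^2),
    LargeDependenceHighGrayLevelEmphasis = acc(function(i, j) i^2 * j^2),
    LargeDependenceLowGrayLevelEmphasis = acc(function(i, j) j^2 / i^2),
    LowGrayLevelEmphasis = acc(function(i, j) 1 / i^2),
    SmallDependenceEmphasis = acc(function(i, j) 1 / j^2),
    SmallDependenceHighGrayLevelEmphasis = acc(function(i, j) i^2 / j^2),
    SmallDependenceLowGrayLevelEmphasis = acc(function(i, j) 1 / (i^2 * j^2)))
}

# ---- statistics ---------------------------------------------------------

oracle_ccc <- function(x, y) {
  n <- length(x)
  sx <- sqrt(mean((x - mean(x))^2))
  sy <- sqrt(mean((y - mean(y))^2))
  rho <- stats::cor(x, y)
  2 * rho * sx * sy / (sx^2 + sy^2 + (mean(x) - mean(y))^2)
}

oracle_icc21 <- function(a, b) {
  df <- data.frame(y = c(a, b),
                   subj = factor(rep(seq_along(a), 2)),
                   rater = factor(rep(1:2, each = length(a))))
  av <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  msr <- av["subj", "Mean Sq"]
  msc <- av["rater", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  n <- length(a); k <- 2
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

oracle_auc <- function(scores, labels) {
  hi <- scores[labels == "high"]; lo <- scores[labels == "low"]
  w <- suppressWarnings(stats::wilcox.test(hi, lo, exact = FALSE))
  unname(w$statistic) / (length(hi) * length(lo))
}

# exact two-sided Mann-Whitney p by enumeration (no ties)
oracle_mw_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, ">"))
  }
  u_obs <- u_of(seq_len(n1))
  all_u <- apply(utils::combn(length(pooled), n1), 2, u_of)
  mid <- n1 * (length(pooled) - n1) / 2
  mean(abs(all_u - mid) >= abs(u_obs - mid))
}
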