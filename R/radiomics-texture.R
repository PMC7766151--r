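# Feature formulas operating on the gray-level matrices produced by the
# compiled builders. Degenerate matrices (single gray level, single run /
# zone / dependence) produce the documented limit values rather than NaN:
# GLCM Correlation and MCC are 1 when the gray-level variance is zero,
# information measures are 0, NGTDM Coarseness is capped at 1e6, Busyness
# and Strength are 0 when their denominators vanish.

glcmFeaturesFromMatrix <- function(P) {
  s <- sum(P)
  ng <- nrow(P)
  p <- P / s
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)                      # == colSums by symmetry
  mu <- sum(seq_len(ng) * px)
  sig2 <- sum((seq_len(ng) - mu)^2 * px)
  # diagonal (difference) and cross-diagonal (sum) probabilities
  kd <- 0:(ng - 1)
  pd <- vapply(kd, function(k) sum(p[abs(i - j) == k]), 0)
  ks <- 2:(2 * ng)
  ps <- vapply(ks, function(k) sum(p[(i + j) == k]), 0)
  da <- sum(kd * pd)
  hx <- -sum(px * log2(px + .EPS))
  hxy <- -sum(p * log2(p + .EPS))
  pxpy <- outer(px, px)
  hxy1 <- -sum(p * log2(pxpy + .EPS))
  hxy2 <- -sum(pxpy * log2(pxpy + .EPS))
  autoc <- sum(i * j * p)

  # maximal correlation coefficient: sqrt of the second largest eigenvalue
  # of Q(i, j) = sum_k p(i,k) p(j,k) / (px(i) px(k))
  keep <- px > 0
  mcc <- if (sum(keep) == 1) 1 else {
    pk <- p[keep, keep, drop = FALSE]
    pxk <- px[keep]
    Q <- sweep(pk, 1, pxk, `/`) %*% t(sweep(pk, 2, pxk, `/`))
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, min(ev[2], 1)))
  }

  c(Autocorrelation = autoc,
    ClusterProminence = sum((i + j - 2 * mu)^4 * p),
    ClusterShade = sum((i + j - 2 * mu)^3 * p),
    ClusterTendency = sum((i + j - 2 * mu)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = if (sig2 > 0) (autoc - mu^2) / sig2 else 1,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pd * log2(pd + .EPS)),
    DifferenceVariance = sum((kd - da)^2 * pd),
    Id = sum(p / (1 + abs(i - j))),
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + (i - j)^2 / ng^2)),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    Imc1 = if (hx > 0) (hxy - hxy1) / hx else 0,
    Imc2 = sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy)))),
    InverseVariance = sum(p[i != j] / (i - j)[i != j]^2),
    JointAverage = mu,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(p),
    SumAverage = sum(ks * ps),
    SumEntropy = -sum(ps * log2(ps + .EPS)),
    SumSquares = sig2)
}

glrlmFeaturesFromMatrix <- function(P, np) {
  nr <- sum(P)
  ng <- nrow(P); nl <- ncol(P)
  i <- matrix(seq_len(ng), ng, nl)
  l <- t(matrix(seq_len(nl), nl, ng))
  pg <- rowSums(P); pl <- colSums(P)
  pn <- P / nr
  mug <- sum(i * pn); mul <- sum(l * pn)
  pr <- pn[pn > 0]
  c(ShortRunEmphasis = sum(P / l^2) / nr,
    LongRunEmphasis = sum(P * l^2) / nr,
    GrayLevelNonUniformity = sum(pg^2) / nr,
    GrayLevelNonUniformityNormalized = sum(pg^2) / nr^2,
    RunLengthNonUniformity = sum(pl^2) / nr,
    RunLengthNonUniformityNormalized = sum(pl^2) / nr^2,
    RunPercentage = nr / np,
    GrayLevelVariance = sum((i - mug)^2 * pn),
    RunVariance = sum((l - mul)^2 * pn),
    RunEntropy = -sum(pr * log2(pr)),
    LowGrayLevelRunEmphasis = sum(P / i^2) / nr,
    HighGrayLevelRunEmphasis = sum(P * i^2) / nr,
    ShortRunLowGrayLevelEmphasis = sum(P / (i^2 * l^2)) / nr,
    ShortRunHighGrayLevelEmphasis = sum(P * i^2 / l^2) / nr,
    LongRunLowGrayLevelEmphasis = sum(P * l^2 / i^2) / nr,
    LongRunHighGrayLevelEmphasis = sum(P * i^2 * l^2) / nr)
}

glszmFeaturesFromMatrix <- function(P, np) {
  nz <- sum(P)
  ng <- nrow(P); ns <- ncol(P)
  i <- matrix(seq_len(ng), ng, ns)
  s <- t(matrix(seq_len(ns), ns, ng))
  pg <- rowSums(P); psz <- colSums(P)
  pn <- P / nz
  mug <- sum(i * pn); mus <- sum(s * pn)
  pr <- pn[pn > 0]
  c(SmallAreaEmphasis = sum(P / s^2) / nz,
    LargeAreaEmphasis = sum(P * s^2) / nz,
    GrayLevelNonUniformity = sum(pg^2) / nz,
    GrayLevelNonUniformityNormalized = sum(pg^2) / nz^2,
    SizeZoneNonUniformity = sum(psz^2) / nz,
    SizeZoneNonUniformityNormalized = sum(psz^2) / nz^2,
    ZonePercentage = nz / np,
    GrayLevelVariance = sum((i - mug)^2 * pn),
    ZoneVariance = sum((s - mus)^2 * pn),
    ZoneEntropy = -sum(pr * log2(pr)),
    LowGrayLevelZoneEmphasis = sum(P / i^2) / nz,
    HighGrayLevelZoneEmphasis = sum(P * i^2) / nz,
    SmallAreaLowGrayLevelEmphasis = sum(P / (i^2 * s^2)) / nz,
    SmallAreaHighGrayLevelEmphasis = sum(P * i^2 / s^2) / nz,
    LargeAreaLowGrayLevelEmphasis = sum(P * s^2 / i^2) / nz,
    LargeAreaHighGrayLevelEmphasis = sum(P * i^2 * s^2) / nz)
}

gldmFeaturesFromMatrix <- function(P, np) {
  nz <- sum(P)
  ng <- nrow(P); nd <- ncol(P)
  i <- matrix(seq_len(ng), ng, nd)
  j <- t(matrix(seq_len(nd), nd, ng))
  pg <- rowSums(P); pd <- colSums(P)
  pn <- P / nz
  mug <- sum(i * pn); mud <- sum(j * pn)
  pr <- pn[pn > 0]
  c(SmallDependenceEmphasis = sum(P / j^2) / nz,
    LargeDependenceEmphasis = sum(P * j^2) / nz,
    GrayLevelNonUniformity = sum(pg^2) / nz,
    DependenceNonUniformity = sum(pd^2) / nz,
    DependenceNonUniformityNormalized = sum(pd^2) / nz^2,
    GrayLevelVariance = sum((i - mug)^2 * pn),
    DependenceVariance = sum((j - mud)^2 * pn),
    DependenceEntropy = -sum(pr * log2(pr)),
    LowGrayLevelEmphasis = sum(P / i^2) / nz,
    HighGrayLevelEmphasis = sum(P * i^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nz)
}

ngtdmFeaturesFromMatrix <- function(M, np) {
  # M: columns n_i, s_i per gray level
  ni <- M[, 1]; si <- M[, 2]
  present <- ni > 0
  iv <- which(present)
  p <- ni[present] / np
  s <- si[present]
  ngp <- length(iv)
  coarseDen <- sum(p * s)
  coarseness <- if (coarseDen > 0) min(1 / coarseDen, 1e6) else 1e6
  if (ngp > 1) {
    dif2 <- outer(iv, iv, `-`)^2
    pp <- outer(p, p)
    contrast <- sum(pp * dif2) / (ngp * (ngp - 1)) * sum(s) / np
    busyDen <- sum(abs(outer(iv * p, iv * p, `-`)))
    busyness <- if (busyDen > 0) coarseDen / busyDen else 0
    num <- outer(p * s, p * s, `+`)
    complexity <- sum(abs(outer(iv, iv, `-`)) * num / outer(p, p, `+`)) / np
    strength <- if (sum(s) > 0) sum(outer(p, p, `+`) * dif2) / sum(s) else 0
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}

#' Texture feature families of a discretized VOI
#'
#' Builds the gray-level matrices in 3D (co-occurrence and run-length over
#' the 13 unique direction pairs with distance 1, symmetric GLCM; size
#' zones and dependences with 26-connectivity; neighborhood differences
#' over the 26-neighborhood) and evaluates the standard feature formulary.
#' GLCM and GLRLM features are averaged over the 13 directions (directions
#' without any voxel pair are skipped).
#'
#' @param levels integer array from [discretize()] (0 outside the mask).
#' @param ng number of gray levels.
#' @param family one of "GLCM", "GLRLM", "GLSZM", "NGTDM", "GLDM".
#' @return named numeric (24/16/16/5/14 values).
#' @export
textureFeatures <- function(levels, ng,
                            family = c("GLCM", "GLRLM", "GLSZM",
                                       "NGTDM", "GLDM")) {
  family <- match.arg(family)
  np <- sum(levels > 0)
  d <- dim(levels)
  switch(family,
    GLCM = {
      ms <- cpp_glcm(as.integer(levels), d, ng)
      feats <- lapply(Filter(function(m) sum(m) > 0, ms),
                      glcmFeaturesFromMatrix)
      Reduce(`+`, feats) / length(feats)
    },
    GLRLM = {
      ms <- cpp_glrlm(as.integer(levels), d, ng)
      feats <- lapply(Filter(function(m) sum(m) > 0, ms),
                      glrlmFeaturesFromMatrix, np = np)
      Reduce(`+`, feats) / length(feats)
    },
    GLSZM = glszmFeaturesFromMatrix(cpp_glszm(as.integer(levels), d, ng), np),
    GLDM = gldmFeaturesFromMatrix(cpp_gldm(as.integer(levels), d, ng), np),
    NGTDM = ngtdmFeaturesFromMatrix(cpp_ngtdm(as.integer(levels), d, ng), np))
}

#' Gray-level texture matrices (for inspection and validation)
#'
#' Returns the raw matrices behind [textureFeatures()]: per-direction
#' GLCM/GLRLM lists, and single GLSZM/GLDM/NGTDM matrices.
#'
#' @inheritParams textureFeatures
#' @return list of matrices (GLCM/GLRLM) or a matrix.
#' @export
textureMatrix <- function(levels, ng,
                          family = c("GLCM", "GLRLM", "GLSZM",
                                     "NGTDM", "GLDM")) {
  family <- match.arg(family)
  d <- dim(levels)
  switch(family,
    GLCM = cpp_glcm(as.integer(levels), d, ng),
    GLRLM = cpp_glrlm(as.integer(levels), d, ng),
    GLSZM = cpp_glszm(as.integer(levels), d, ng),
    GLDM = cpp_gldm(as.integer(levels), d, ng),
    NGTDM = cpp_ngtdm(as.integer(levels), d, ng))
}
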