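#' First-order intensity statistics of a VOI
#'
#' The 18 standard first-order features of the voxel intensities inside
#' the mask. Energy is the plain sum of squared intensities (no intensity
#' shift: SUV 0 is meaningful); TotalEnergy scales Energy by the voxel
#' volume in mm^3. Entropy and Uniformity are computed on the absolute
#' discretized histogram ([discretize()]); percentiles use linear
#' interpolation. Skewness and Kurtosis are the population moment ratios
#' (Kurtosis not excess-corrected); a constant VOI yields 0 for both by
#' convention.
#'
#' @param image 3D array or [SummedImage-class].
#' @param mask logical array or [VOIMask-class], non-empty.
#' @param voxelSize numeric(3) mm (from the image if a SummedImage).
#' @param binWidth,origin discretization for Entropy/Uniformity.
#' @return named numeric of length 18.
#' @export
firstOrderFeatures <- function(image, mask, voxelSize = NULL,
                               binWidth = 0.15, origin = 0) {
  if (is(image, "SummedImage")) {
    voxelSize <- image@voxelSize
    image <- image@values
  }
  if (is(mask, "VOIMask")) {
    voxelSize <- voxelSize %||% mask@voxelSize
    mask <- mask@mask
  }
  stopifnot(any(mask), length(voxelSize) == 3)
  v <- image[mask]
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  p10 <- unname(stats::quantile(v, 0.10, type = 7))
  p90 <- unname(stats::quantile(v, 0.90, type = 7))
  mid <- v[v >= p10 & v <= p90]
  disc <- discretize(array(v, c(n, 1, 1)), array(TRUE, c(n, 1, 1)),
                     binWidth, origin)
  pr <- tabulate(disc$levels, disc$ng) / n
  pr <- pr[pr > 0]
  c(Energy = sum(v^2),
    TotalEnergy = prod(voxelSize) * sum(v^2),
    Entropy = -sum(pr * log2(pr)),
    Minimum = min(v),
    Percentile10 = p10,
    Percentile90 = p90,
    Maximum = max(v),
    Mean = mu,
    Median = stats::median(v),
    InterquartileRange = unname(stats::quantile(v, 0.75, type = 7) -
                                  stats::quantile(v, 0.25, type = 7)),
    Range = max(v) - min(v),
    MeanAbsoluteDeviation = mean(abs(v - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(mid - mean(mid))),
    RootMeanSquared = sqrt(mean(v^2)),
    Skewness = if (m2 > 0) mean((v - mu)^3) / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) mean((v - mu)^4) / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(pr^2))
}

# boundary voxels of a mask (those with at least one 6-neighbour outside)
maskBoundary <- function(mask) {
  d <- dim(mask)
  inner <- mask
  shift1 <- function(m, a, s) {
    out <- array(FALSE, d)
    n <- d[a]
    src <- if (s > 0) 1:(n - 1) else 2:n
    dst <- if (s > 0) 2:n else 1:(n - 1)
    ix <- rep(list(quote(expr = )), 3)
    ixs <- ix; ixs[[a]] <- src
    ixd <- ix; ixd[[a]] <- dst
    out <- do.call(`[<-`, c(list(out), ixd, list(do.call(`[`, c(list(m), ixs)))))
    out
  }
  for (a in 1:3) for (s in c(1, -1)) inner <- inner & shift1(mask, a, s)
  mask & !inner
}

#' Shape features of a VOI
#'
#' The 14 standard 3D shape descriptors from the mask and voxel spacing,
#' using voxel approximations: volume is voxel count times voxel volume
#' (the face-mesh enclosing the voxels encloses exactly this volume, so
#' MeshVolume equals VoxelVolume here), surface area counts exposed voxel
#' faces, and the maximum diameters are the largest pairwise distances
#' between boundary voxel centers (overall and within planes orthogonal to
#' each axis). Axis lengths are 4*sqrt(eigenvalue) of the sample
#' covariance (divisor n-1) of the voxel-center physical coordinates.
#' A single-voxel mask has undefined axes, reported as 0 with a warning.
#'
#' @param mask logical array or [VOIMask-class], non-empty.
#' @param voxelSize numeric(3) mm.
#' @return named numeric of length 14.
#' @export
shapeFeatures <- function(mask, voxelSize = NULL) {
  if (is(mask, "VOIMask")) {
    voxelSize <- voxelSize %||% mask@voxelSize
    mask <- mask@mask
  }
  stopifnot(any(mask), length(voxelSize) == 3)
  d <- dim(mask)
  n <- sum(mask)
  vol <- n * prod(voxelSize)

  # exposed-face surface area
  area <- 0
  faceArea <- c(voxelSize[2] * voxelSize[3], voxelSize[1] * voxelSize[3],
                voxelSize[1] * voxelSize[2])
  for (a in 1:3) {
    m <- aperm(mask, c(a, setdiff(1:3, a)))
    dm <- dim(m)
    dim(m) <- c(dm[1], prod(dm[2:3]))
    padded <- rbind(FALSE, m, FALSE)
    exposed <- sum(padded[-1, , drop = FALSE] != padded[-nrow(padded), , drop = FALSE])
    area <- area + exposed * faceArea[a]
  }

  ind <- which(mask, arr.ind = TRUE)
  coords <- sweep(ind - 1, 2, voxelSize, `*`)

  # principal axes from the sample covariance of voxel centers
  if (n >= 2) {
    ev <- sort(eigen(stats::cov(coords), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
    major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2]); least <- 4 * sqrt(ev[3])
    elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0
    flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0
  } else {
    warning("single-voxel mask: axis features undefined, reported as 0")
    major <- minor <- least <- elong <- flat <- 0
  }

  bnd <- maskBoundary(mask)
  bc <- which(bnd, arr.ind = TRUE)
  bc <- sweep(bc - 1, 2, voxelSize, `*`)
  maxDist <- function(xy) {
    if (nrow(xy) < 2) return(0)
    sqrt(max(as.numeric(stats::dist(xy))^2))
  }
  diam3d <- maxDist(bc)
  planeDiam <- function(fixedAxis) {
    groups <- split.data.frame(bc[, -fixedAxis, drop = FALSE], bc[, fixedAxis])
    max(vapply(groups, maxDist, 0))
  }
  c(MeshVolume = vol,
    VoxelVolume = vol,
    SurfaceArea = area,
    SurfaceVolumeRatio = area / vol,
    Sphericity = (36 * pi * vol^2)^(1 / 3) / area,
    Maximum3DDiameter = diam3d,
    Maximum2DDiameterSlice = planeDiam(3),   # in-plane (x, y)
    Maximum2DDiameterColumn = planeDiam(2),  # (x, z)
    Maximum2DDiameterRow = planeDiam(1),     # (y, z)
    MajorAxisLength = major,
    MinorAxisLength = minor,
    LeastAxisLength = least,
    Elongation = elong,
    Flatness = flat)
}
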