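# --- separable convolution along one array axis ---------------------------
# output[i] = sum_j k[j] * x[i + j - center]; boundary "reflect" mirrors
# about the edge (half-sample symmetric), "periodic" wraps.
convolveAxis <- function(x, k, axis, center = (length(k) + 1L) %/% 2L,
                         boundary = c("reflect", "periodic")) {
  boundary <- match.arg(boundary)
  d <- dim(x)
  perm <- c(axis, setdiff(seq_along(d), axis))
  xp <- aperm(x, perm)
  n <- d[axis]
  m <- length(xp) / n
  dim(xp) <- c(n, m)
  y <- matrix(0, n, m)
  for (j in seq_along(k)) {
    idx <- seq_len(n) + j - center
    if (boundary == "periodic") {
      idx <- ((idx - 1L) %% n) + 1L
    } else {
      idx <- ifelse(idx < 1L, 1L - idx, idx)
      idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)
    }
    y <- y + k[j] * xp[idx, , drop = FALSE]
  }
  dim(y) <- d[perm]
  aperm(y, order(perm))
}

# sampled 1D Gaussian (normalized to unit sum) and its second derivative
# (quadrature-weighted, mean-corrected to zero DC so constants map to 0)
logKernels1D <- function(sigma, spacing) {
  r <- max(2L, ceiling(4 * sigma / spacing))
  x <- (-r:r) * spacing
  g <- exp(-x^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  g <- g / sum(g)
  g2 <- exp(-x^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi)) *
    (x^2 - sigma^2) / sigma^4 * spacing
  g2 <- g2 - mean(g2)
  list(g = g, g2 = g2)
}

#' Laplacian-of-Gaussian filter with physical-unit sigma
#'
#' 3D LoG on the native grid: the separable sum of second-derivative
#' Gaussian kernels, one axis at a time. Kernels are sampled from the
#' analytic Gaussian derivatives at voxel centers (sigma in mm, converted
#' per axis via the voxel spacing), normalized so the smoothing kernels
#' have unit gain, and DC-corrected so a constant image maps to zero.
#' Boundaries are mirrored.
#'
#' @param image 3D array or [SummedImage-class].
#' @param voxelSize numeric(3) mm (taken from the image if a SummedImage).
#' @param sigma Gaussian scale in mm, default 0.5.
#' @return filtered 3D array (same grid).
#' @export
logFilter <- function(image, voxelSize = NULL, sigma = 0.5) {
  if (is(image, "SummedImage")) {
    voxelSize <- image@voxelSize
    image <- image@values
  }
  stopifnot(length(voxelSize) == 3)
  ks <- lapply(1:3, function(a) logKernels1D(sigma, voxelSize[a]))
  out <- array(0, dim(image))
  for (a in 1:3) {
    y <- image
    for (b in 1:3) {
      k <- if (b == a) ks[[b]]$g2 else ks[[b]]$g
      y <- convolveAxis(y, k, b, boundary = "reflect")
    }
    out <- out + y
  }
  out
}

# coif1 analysis filters (6 taps)
COIF1_LO <- c(-0.015655728135791993, -0.07273261951252645,
              0.3848648468648578, 0.8525720202116004,
              0.3378976624574818, -0.07273261951252645)
COIF1_HI <- c(0.07273261951252645, 0.3378976624574818,
              -0.8525720202116004, 0.3848648468648578,
              0.07273261951252645, -0.015655728135791993)

#' Single-level undecimated 3D wavelet decomposition (coif1)
#'
#' Applies the coif1 low- (L) and high-pass (H) analysis filters along each
#' axis in all eight combinations, without downsampling, so every sub-band
#' image shares the grid of the input. Band names give the filter per axis
#' in (x, y, z) order, LLL through HHH. Boundaries are periodic.
#'
#' @param image 3D array or [SummedImage-class].
#' @return named list of eight 3D arrays.
#' @export
waveletDecompose <- function(image) {
  if (is(image, "SummedImage")) image <- image@values
  stopifnot(length(dim(image)) == 3)
  bandNames <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
  out <- vector("list", 8)
  names(out) <- bandNames
  for (b in bandNames) {
    y <- image
    flt <- strsplit(b, "")[[1]]
    for (a in 1:3) {
      k <- if (flt[a] == "L") COIF1_LO else COIF1_HI
      y <- convolveAxis(y, k, a, center = 3L, boundary = "periodic")
    }
    out[[b]] <- y
  }
  out
}

#' Absolute intensity discretization
#'
#' Bins SUV (or filtered intensity) values with a fixed absolute bin width:
#' level(v) = floor((v - origin)/binWidth) + 1, clamped below at 1. Voxels
#' outside the mask get level 0; the number of gray levels is the maximum
#' level inside the mask.
#'
#' @param image 3D array or [SummedImage-class].
#' @param mask logical array or [VOIMask-class], non-empty.
#' @param binWidth bin width in intensity units, default 0.15 SUV.
#' @param origin bin origin, default 0.
#' @return list with \code{levels} (integer array, 0 outside mask) and
#'   \code{ng} (number of gray levels).
#' @export
discretize <- function(image, mask, binWidth = 0.15, origin = 0) {
  if (is(image, "SummedImage")) image <- image@values
  if (is(mask, "VOIMask")) mask <- mask@mask
  stopifnot(binWidth > 0, any(mask))
  lev <- pmax(1L, as.integer(floor((image - origin) / binWidth)) + 1L)
  lev[!mask] <- 0L
  dim(lev) <- dim(image)
  list(levels = lev, ng = max(lev))
}
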