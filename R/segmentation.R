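#' Duration-weighted summed image over a time window
#'
#' Averages the frames of a dynamic series whose intervals lie within the
#' window, weighting by frame duration. The default 20--40 min window
#' covers exactly the four 5-min late frames of the standard schedule.
#'
#' @param series a [DynamicPETSeries-class].
#' @param start,end window boundaries in minutes; must coincide with frame
#'   boundaries.
#' @return a [SummedImage-class].
#' @export
sumWindow <- function(series, start = 20, end = 40) {
  stopifnot(is(series, "DynamicPETSeries"))
  s <- series@schedule
  ends <- s@starts + s@durations
  sel <- s@starts >= start - 1e-9 & ends <= end + 1e-9
  if (!any(abs(s@starts - start) < 1e-9) || !any(abs(ends - end) < 1e-9))
    stop("window boundaries must coincide with frame boundaries")
  w <- s@durations[sel] / sum(s@durations[sel])
  d <- dim(series@values)[1:3]
  vals <- array(0, d)
  idx <- which(sel)
  for (k in seq_along(idx))
    vals <- vals + w[k] * series@values[, , , idx[k]]
  new("SummedImage", values = vals, voxelSize = series@voxelSize,
      window = c(start, end))
}

# logical sphere on the image grid by voxel-center distance; world
# coordinate of voxel i along axis a is (i-1) * voxelSize[a]
sphereMask <- function(gridShape, voxelSize, center, radius) {
  co <- axisCoords(gridShape, voxelSize)
  d2 <- outer(outer((co[[1]] - center[1])^2, (co[[2]] - center[2])^2, "+"),
              (co[[3]] - center[3])^2, "+")
  d2 <= radius^2
}

#' Spherical background VOI in normal-appearing brain
#'
#' A 30 mm diameter (14 mL) sphere of voxels whose centers lie within the
#' radius of the given center, used as the healthy-brain reference region.
#' The center is an explicit argument because its placement in the
#' contralesional hemisphere is a manual act on clinical data; the phantom
#' supplies it.
#'
#' @param image a [SummedImage-class].
#' @param center world coordinates in mm.
#' @param diameter sphere diameter in mm, default 30.
#' @return a [VOIMask-class] with provenance "background".
#' @export
backgroundVOI <- function(image, center, diameter = 30) {
  stopifnot(is(image, "SummedImage"))
  d <- dim(image@values)
  r <- diameter / 2
  ext <- d * image@voxelSize
  if (any(center - r < -1e-9) || any(center + r > ext + 1e-9))
    stop("background sphere is clipped by the image grid")
  m <- sphereMask(d, image@voxelSize, center, r)
  new("VOIMask", mask = m, voxelSize = image@voxelSize,
      provenance = "background", threshold = NA_real_)
}

#' Mean SUV within a VOI
#' @param image a [SummedImage-class].
#' @param voi a [VOIMask-class].
#' @return mean SUV over the VOI voxels.
#' @export
voiMean <- function(image, voi) {
  stopifnot(is(image, "SummedImage"), is(voi, "VOIMask"))
  if (!any(voi@mask)) stop("empty VOI")
  mean(image@values[voi@mask])
}

#' TBR iso-contour auto-segmentation of the tumor volume
#'
#' Thresholds the summed image at \code{threshold} times the background
#' mean (inclusive: a voxel exactly at the threshold is included),
#' restricted to a search region, and keeps the largest 26-connected
#' component. An empty mask is a legitimate result (no uptake above
#' threshold).
#'
#' @param image a [SummedImage-class].
#' @param bgMean background mean SUV (> 0).
#' @param threshold TBR threshold, default 1.6.
#' @param searchRegion logical array or [VOIMask-class] restricting the
#'   segmentation; NULL searches the whole grid.
#' @return a [VOIMask-class] with provenance "tumor".
#' @export
autocontour <- function(image, bgMean, threshold = 1.6, searchRegion = NULL) {
  stopifnot(is(image, "SummedImage"), bgMean > 0)
  m <- image@values / bgMean >= threshold
  if (!is.null(searchRegion)) {
    sr <- if (is(searchRegion, "VOIMask")) searchRegion@mask else searchRegion
    m <- m & sr
  }
  if (any(m)) {
    lab <- array(cpp_label26(as.logical(m), dim(m)), dim(m))
    counts <- tabulate(lab[lab > 0])
    m <- lab == which.max(counts)
  }
  new("VOIMask", mask = m, voxelSize = image@voxelSize,
      provenance = "tumor", threshold = threshold)
}

#' Segmentation augmentation at three TBR thresholds
#'
#' Builds the tumor VOI at the conventional threshold 1.6 and at thresholds
#' 10\% lower (1.4) and higher (1.8), tripling the number of datasets per
#' patient. The masks are nested: mask(1.8) within mask(1.6) within
#' mask(1.4).
#'
#' @inheritParams autocontour
#' @param thresholds TBR thresholds, default c(1.4, 1.6, 1.8).
#' @return a named list of [VOIMask-class], one per threshold.
#' @export
augmentSegmentations <- function(image, bgMean, searchRegion = NULL,
                                 thresholds = c(1.4, 1.6, 1.8)) {
  out <- lapply(thresholds, function(t)
    autocontour(image, bgMean, t, searchRegion))
  names(out) <- sprintf("tbr_%g", thresholds)
  out
}

#' 16 mm sphere at the hottest tumor voxel
#'
#' A 16 mm diameter (2 mL) spherical VOI centered on the voxel with the
#' maximum uptake inside \code{within}; ties are broken toward the lowest
#' linear index. The sphere may extend beyond \code{within} and is clipped
#' only by the image grid.
#'
#' @param image a [SummedImage-class].
#' @param within a non-empty [VOIMask-class] (typically the tumor VOI).
#' @param diameter sphere diameter in mm, default 16.
#' @return a [VOIMask-class] with provenance "peak_sphere".
#' @export
peakSphere <- function(image, within, diameter = 16) {
  stopifnot(is(image, "SummedImage"), is(within, "VOIMask"))
  if (!any(within@mask)) stop("no tumor voxels")
  v <- image@values
  v[!within@mask] <- -Inf
  peak <- which.max(v)   # lowest linear index on ties
  d <- dim(v)
  ijk <- arrayInd(peak, d)
  center <- (as.numeric(ijk) - 1) * image@voxelSize
  m <- sphereMask(d, image@voxelSize, center, diameter / 2)
  new("VOIMask", mask = m, voxelSize = image@voxelSize,
      provenance = "peak_sphere", threshold = NA_real_)
}
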