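#' Mean tumor-to-brain ratio
#'
#' Mean SUV of the tumor VOI divided by the mean SUV of the background VOI,
#' both on the summed 20--40 min image.
#'
#' @param summed a [SummedImage-class].
#' @param tumorVoi non-empty tumor [VOIMask-class].
#' @param bgVoi background [VOIMask-class].
#' @return dimensionless TBRmean.
#' @export
tbrMean <- function(summed, tumorVoi, bgVoi) {
  voiMean(summed, tumorVoi) / voiMean(summed, bgVoi)
}

#' Maximum tumor-to-brain ratio
#'
#' Mean SUV of the 16 mm peak sphere (not the single hottest voxel)
#' divided by the background mean.
#'
#' @param summed a [SummedImage-class].
#' @param peakVoi the peak-sphere [VOIMask-class] from [peakSphere()].
#' @param bgVoi background [VOIMask-class].
#' @return dimensionless TBRmax.
#' @export
tbrMax <- function(summed, peakVoi, bgVoi) {
  voiMean(summed, peakVoi) / voiMean(summed, bgVoi)
}

#' Time-activity curve of a VOI
#'
#' Mean SUV within the VOI for every frame of the dynamic series.
#'
#' @param series a [DynamicPETSeries-class].
#' @param voi a non-empty [VOIMask-class].
#' @return a [TACurve-class].
#' @export
extractTAC <- function(series, voi) {
  stopifnot(is(series, "DynamicPETSeries"), is(voi, "VOIMask"))
  if (!any(voi@mask)) stop("empty VOI")
  nf <- dim(series@values)[4]
  mu <- vapply(seq_len(nf),
               function(f) mean(series@values[, , , f][voi@mask]), 0)
  new("TACurve", midTimes = series@schedule@midTimes, meanSUV = mu,
      provenance = voi@provenance)
}

#' Time-to-peak of a time-activity curve
#'
#' Mid-time of the frame with the maximal mean SUV; ties are broken toward
#' the earlier frame. A steadily increasing curve therefore returns the
#' final mid-time (37.5 min on the standard schedule), matching the
#' convention that the end of the acquisition is the TTP when no maximum
#' is identifiable.
#'
#' @param tac a [TACurve-class].
#' @return TTP in minutes, an element of the mid-time grid.
#' @export
timeToPeak <- function(tac) {
  stopifnot(is(tac, "TACurve"))
  tac@midTimes[which.max(tac@meanSUV)]
}

#' Late-window slope of a time-activity curve
#'
#' Ordinary least-squares slope of mean SUV against frame mid-time over the
#' frames whose mid-times fall in the window (20--40 min by default),
#' converted from SUV/min to SUV/h.
#'
#' @param tac a [TACurve-class].
#' @param start,end window in minutes.
#' @return slope in SUV per hour.
#' @export
tacSlope <- function(tac, start = 20, end = 40) {
  stopifnot(is(tac, "TACurve"))
  sel <- tac@midTimes >= start & tac@midTimes <= end
  if (sum(sel) < 2) stop("need at least two frames in the window")
  fit <- stats::lm.fit(cbind(1, tac@midTimes[sel]),
                       tac@meanSUV[sel])
  unname(fit$coefficients[2]) * 60
}

#' Conventional FET PET parameters of one patient
#'
#' Full conventional workflow on a dynamic series: summed 20--40 min
#' image, background VOI at the supplied center, TBR 1.6 auto-contour
#' within the search region, 16 mm peak sphere, then TBRmean, TBRmax, and
#' the dynamic parameters TTP and slope from the peak-sphere TAC.
#'
#' @param series a [DynamicPETSeries-class].
#' @param bgCenter background sphere center, world mm.
#' @param searchRegion logical array or [VOIMask-class] for the
#'   auto-contour.
#' @param threshold TBR threshold for the tumor VOI, default 1.6.
#' @return a list: tbr_mean, tbr_max, ttp (min), slope (SUV/h), plus the
#'   tumor/peak/background VOIs and the summed image.
#' @export
conventionalParams <- function(series, bgCenter, searchRegion = NULL,
                               threshold = 1.6) {
  summed <- sumWindow(series)
  bg <- backgroundVOI(summed, bgCenter)
  bgMean <- voiMean(summed, bg)
  tumor <- autocontour(summed, bgMean, threshold, searchRegion)
  if (!any(tumor@mask))
    stop("no tumor voxels above threshold ", threshold)
  peak <- peakSphere(summed, tumor)
  tac <- extractTAC(series, peak)
  list(tbr_mean = tbrMean(summed, tumor, bg),
       tbr_max = tbrMax(summed, peak, bg),
       ttp = timeToPeak(tac),
       slope = tacSlope(tac),
       tumorVoi = tumor, peakVoi = peak, bgVoi = bg, summed = summed)
}

#' Static parameters from a summed image
#'
#' TBRmean and TBRmax (and the hottest-voxel TBR) when only the summed
#' 20--40 min image is available; the dynamic parameters require the full
#' series.
#'
#' @param summed a [SummedImage-class].
#' @inheritParams conventionalParams
#' @return a list: tbr_mean, tbr_max, tbr_peak_voxel, and the VOIs.
#' @export
staticParams <- function(summed, bgCenter, searchRegion = NULL,
                         threshold = 1.6) {
  bg <- backgroundVOI(summed, bgCenter)
  bgMean <- voiMean(summed, bg)
  tumor <- autocontour(summed, bgMean, threshold, searchRegion)
  if (!any(tumor@mask))
    stop("no tumor voxels above threshold ", threshold)
  peak <- peakSphere(summed, tumor)
  list(tbr_mean = tbrMean(summed, tumor, bg),
       tbr_max = tbrMax(summed, peak, bg),
       tbr_peak_voxel = max(summed@values[tumor@mask]) / bgMean,
       tumorVoi = tumor, peakVoi = peak, bgVoi = bg)
}
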