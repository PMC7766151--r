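#' @import methods
NULL

#' Acquisition frame schedule of a dynamic PET scan
#'
#' Timing of the reconstructed time frames of a dynamic acquisition, in
#' minutes post-injection. Frames must be contiguous, non-overlapping and
#' start at 0; mid-frame times are \code{start + duration/2}.
#'
#' @slot starts numeric, frame start times (min).
#' @slot durations numeric, frame durations (min).
#' @slot midTimes numeric, frame mid-times (min), strictly increasing.
#' @seealso [frameSchedule()] for the standard 40-min, 14-frame protocol.
#' @export
setClass("FrameSchedule",
  representation(starts = "numeric", durations = "numeric",
                 midTimes = "numeric"))

setValidity("FrameSchedule", function(object) {
  s <- object@starts; d <- object@durations; m <- object@midTimes
  if (length(s) != length(d) || length(s) != length(m))
    return("starts, durations and midTimes must have equal length")
  if (length(s) == 0) return("schedule must contain at least one frame")
  if (any(d <= 0)) return("frame durations must be positive")
  if (abs(s[1]) > 1e-9) return("first frame must start at 0")
  if (length(s) > 1 && any(abs(s[-1] - (s + d)[-length(s)]) > 1e-9))
    return("frames must be contiguous and non-overlapping")
  if (any(abs(m - (s + d / 2)) > 1e-9))
    return("midTimes must equal starts + durations/2")
  if (any(diff(m) <= 0)) return("midTimes must be strictly increasing")
  TRUE
})

#' 4D dynamic PET volume in SUV units
#'
#' A dynamic PET series: a 4D array indexed (x, y, z, frame) holding
#' standardized uptake values, the physical voxel size in mm, and the frame
#' schedule of the acquisition.
#'
#' @slot values 4D numeric array of SUV, non-negative.
#' @slot voxelSize numeric(3), voxel edge lengths in mm.
#' @slot schedule a [FrameSchedule-class] whose length equals dim(values)[4].
#' @export
setClass("DynamicPETSeries",
  representation(values = "array", voxelSize = "numeric",
                 schedule = "FrameSchedule"))

setValidity("DynamicPETSeries", function(object) {
  v <- object@values
  if (length(dim(v)) != 4) return("values must be a 4D array (x, y, z, frame)")
  if (any(v < 0)) return("SUV values must be non-negative")
  if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
    return("voxelSize must be three positive lengths in mm")
  if (dim(v)[4] != length(object@schedule@starts))
    return("frame count must equal the schedule length")
  TRUE
})

#' Time-window averaged 3D PET image
#'
#' Duration-weighted mean of the frames of a dynamic series over a time
#' window, conventionally 20--40 min post-injection for FET.
#'
#' @slot values 3D numeric array of SUV.
#' @slot voxelSize numeric(3), mm.
#' @slot window numeric(2), start and end of the averaging window (min).
#' @export
setClass("SummedImage",
  representation(values = "array", voxelSize = "numeric", window = "numeric"))

setValidity("SummedImage", function(object) {
  if (length(dim(object@values)) != 3) return("values must be a 3D array")
  if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
    return("voxelSize must be three positive lengths in mm")
  if (length(object@window) != 2 || diff(object@window) <= 0)
    return("window must be an increasing (start, end) pair in minutes")
  TRUE
})

#' Volume-of-interest mask
#'
#' A boolean 3D voxel mask sharing the grid of its source image, together
#' with its provenance (background sphere, TBR iso-contour tumor VOI at a
#' given threshold, or peak sphere).
#'
#' @slot mask logical 3D array.
#' @slot voxelSize numeric(3), mm.
#' @slot provenance one of "background", "tumor", "peak_sphere".
#' @slot threshold TBR threshold for tumor VOIs, NA otherwise.
#' @export
setClass("VOIMask",
  representation(mask = "array", voxelSize = "numeric",
                 provenance = "character", threshold = "numeric"))

setValidity("VOIMask", function(object) {
  if (length(dim(object@mask)) != 3 || !is.logical(object@mask))
    return("mask must be a logical 3D array")
  if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
    return("voxelSize must be three positive lengths in mm")
  if (!object@provenance %in% c("background", "tumor", "peak_sphere"))
    return("provenance must be background, tumor or peak_sphere")
  # only a tumor iso-contour may legitimately be empty
  if (object@provenance != "tumor" && !any(object@mask))
    return("non-tumor VOI must contain at least one voxel")
  TRUE
})

#' Time-activity curve
#'
#' Mean SUV within a VOI per frame of a dynamic acquisition.
#'
#' @slot midTimes numeric, frame mid-times (min).
#' @slot meanSUV numeric, mean SUV per frame.
#' @slot provenance character, VOI the curve was extracted from.
#' @export
setClass("TACurve",
  representation(midTimes = "numeric", meanSUV = "numeric",
                 provenance = "character"))

setValidity("TACurve", function(object) {
  if (length(object@midTimes) != length(object@meanSUV))
    return("midTimes and meanSUV must have equal length")
  if (any(!is.finite(object@meanSUV))) return("meanSUV must be finite")
  TRUE
})

#' Class-conditional kinetic parameters of the lesion phantom
#'
#' Generative parameters of one diagnostic class (early tumor progression or
#' pseudoprogression): the class-conditional distribution of the peak
#' tumor-to-brain ratio, the time-to-peak regime of the time-activity curve,
#' the late-window slope distribution, and the multiplicative uptake
#' heterogeneity of the lesion texture.
#'
#' @slot label "EP" or "PSP".
#' @slot peakTbrMean,peakTbrSd mean/sd of the peak TBR (dimensionless).
#' @slot ttpMode "early" (TAC peaks in frames 8--10 then declines) or "late"
#'   (TAC increases through the end of the acquisition).
#' @slot slopeMean,slopeSd mean/sd of the 20--40 min TAC slope (SUV/h).
#' @slot heterogeneityAmplitude multiplicative amplitude of the smooth random
#'   uptake field, fraction of lesion SUV in [0, 0.5].
#' @slot heterogeneityLength correlation length of that field (mm).
#' @export
setClass("KineticClassParams",
  representation(label = "character",
                 peakTbrMean = "numeric", peakTbrSd = "numeric",
                 ttpMode = "character",
                 slopeMean = "numeric", slopeSd = "numeric",
                 heterogeneityAmplitude = "numeric",
                 heterogeneityLength = "numeric"))

setValidity("KineticClassParams", function(object) {
  if (!object@label %in% c("EP", "PSP")) return("label must be EP or PSP")
  if (!object@ttpMode %in% c("early", "late"))
    return("ttpMode must be early or late")
  if (object@peakTbrMean <= 1.6)
    return("peakTbrMean must exceed 1.6 so the lesion is segmentable")
  if (object@heterogeneityAmplitude < 0 || object@heterogeneityAmplitude > 0.5)
    return("heterogeneityAmplitude must lie in [0, 0.5]")
  if (object@peakTbrSd < 0 || object@slopeSd < 0 ||
      object@heterogeneityLength <= 0)
    return("scale parameters must be positive")
  TRUE
})

#' Geometry and noise specification of the digital FET PET phantom
#'
#' Describes one simulated cohort: grid and voxel geometry, patient counts
#' per class, background uptake, lesion size range, the per-frame noise
#' scale, and the master seed from which per-patient seeds are derived.
#'
#' @slot gridShape integer(3), voxels per axis.
#' @slot voxelSize numeric(3), mm (default 2.0 x 2.0 x 2.4).
#' @slot nEP,nPSP patients per class.
#' @slot backgroundSUV background (healthy brain) SUV, default 1.0.
#' @slot lesionRadiusRange numeric(2), lesion semi-axis range in mm.
#' @slot noiseSdPerMinute Gaussian noise scale in SUV*sqrt(min); a frame of
#'   duration d has voxel noise sd \code{noiseSdPerMinute/sqrt(d)}.
#' @slot seed integer master seed.
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", voxelSize = "numeric",
                 nEP = "integer", nPSP = "integer",
                 backgroundSUV = "numeric", lesionRadiusRange = "numeric",
                 noiseSdPerMinute = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (length(object@gridShape) != 3 || any(object@gridShape < 8))
    return("gridShape must be three voxel counts")
  if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
    return("voxelSize must be three positive lengths in mm")
  if (object@nEP + object@nPSP < 2)
    return("cohort must contain at least two patients")
  if (object@backgroundSUV <= 0) return("backgroundSUV must be positive")
  if (length(object@lesionRadiusRange) != 2 ||
      diff(object@lesionRadiusRange) < 0 || object@lesionRadiusRange[1] <= 0)
    return("lesionRadiusRange must be an increasing positive pair (mm)")
  if (object@noiseSdPerMinute < 0) return("noiseSdPerMinute must be >= 0")
  ext <- object@gridShape * object@voxelSize
  # contralesional half must hold the 30 mm background sphere,
  # the other half the largest lesion
  if (ext[1] / 2 < 30 + 4 || any(ext[2:3] < 34))
    return("grid too small for a 30 mm background sphere in one hemisphere")
  if (ext[1] / 2 < 2 * object@lesionRadiusRange[2] + 8)
    return("grid too small to hold the largest lesion in one hemisphere")
  TRUE
})

#' Cut-off rule for a conventional FET PET parameter
#'
#' A decision rule "predict pseudoprogression when the parameter is
#' below/above the cut-off". Directions follow the field conventions:
#' TBRmean/TBRmax use inclusive \code{le}, TTP inclusive \code{ge}, slope
#' strict \code{gt}.
#'
#' @slot parameter column name of the parameter.
#' @slot cutoff numeric cut-off value.
#' @slot direction "le", "ge" or "gt" (the side predicting pseudoprogression).
#' @export
setClass("CutoffRule",
  representation(parameter = "character", cutoff = "numeric",
                 direction = "character"))

setValidity("CutoffRule", function(object) {
  if (!object@direction %in% c("le", "ge", "gt"))
    return("direction must be one of le, ge, gt")
  if (!is.finite(object@cutoff)) return("cutoff must be finite")
  TRUE
})

#' Confusion-matrix derived classification metrics
#'
#' Counts and derived metrics of a binary classifier with pseudoprogression
#' as the positive class. Metrics with a zero denominator are NA
#' (undefined), never 0.
#'
#' @slot tp,fp,fn,tn confusion counts.
#' @slot metrics named numeric: sensitivity, specificity, ppv, npv, fnr,
#'   fpr, accuracy, f1, mcc, auc (auc is NA when no score is available).
#' @export
setClass("ClassificationMetrics",
  representation(tp = "numeric", fp = "numeric", fn = "numeric",
                 tn = "numeric", metrics = "numeric"))

setValidity("ClassificationMetrics", function(object) {
  need <- c("sensitivity", "specificity", "ppv", "npv", "fnr", "fpr",
            "accuracy", "f1", "mcc", "auc")
  if (!all(need %in% names(object@metrics)))
    return(paste("metrics must contain:", paste(need, collapse = ", ")))
  m <- object@metrics
  frac <- m[c("sensitivity", "specificity", "ppv", "npv", "fnr", "fpr",
              "accuracy")]
  if (any(frac < -1e-12 | frac > 1 + 1e-12, na.rm = TRUE))
    return("fractional metrics must lie in [0, 1]")
  if (!is.na(m["mcc"]) && abs(m["mcc"]) > 1 + 1e-12)
    return("mcc must lie in [-1, 1]")
  TRUE
})
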