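#' Accessors for the imaging containers
#'
#' Small accessor generics used across the package instead of direct slot
#' access: \code{suvValues} returns the SUV array of a series or summed
#' image, \code{voxelSize} the physical voxel size in mm, \code{schedule}
#' the frame schedule, \code{maskArray} the logical array of a VOI, and
#' \code{provenance} how a VOI was constructed.
#'
#' @param object a package object.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("suvValues", function(object) standardGeneric("suvValues"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("schedule", function(object) standardGeneric("schedule"))
#' @rdname accessors
#' @export
setGeneric("maskArray", function(object) standardGeneric("maskArray"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("midTimes", function(object) standardGeneric("midTimes"))
#' @rdname accessors
#' @export
setGeneric("frameDurations", function(object) standardGeneric("frameDurations"))
#' @rdname accessors
#' @export
setGeneric("voxelVolume", function(object) standardGeneric("voxelVolume"))

#' @rdname accessors
#' @export
setMethod("suvValues", "DynamicPETSeries", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("suvValues", "SummedImage", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("voxelSize", "DynamicPETSeries", function(object) object@voxelSize)
#' @rdname accessors
#' @export
setMethod("voxelSize", "SummedImage", function(object) object@voxelSize)
#' @rdname accessors
#' @export
setMethod("voxelSize", "VOIMask", function(object) object@voxelSize)
#' @rdname accessors
#' @export
setMethod("schedule", "DynamicPETSeries", function(object) object@schedule)
#' @rdname accessors
#' @export
setMethod("maskArray", "VOIMask", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("provenance", "VOIMask", function(object) object@provenance)
#' @rdname accessors
#' @export
setMethod("midTimes", "FrameSchedule", function(object) object@midTimes)
#' @rdname accessors
#' @export
setMethod("midTimes", "TACurve", function(object) object@midTimes)
#' @rdname accessors
#' @export
setMethod("frameDurations", "FrameSchedule", function(object) object@durations)
#' @rdname accessors
#' @export
setMethod("voxelVolume", "VOIMask",
          function(object) prod(object@voxelSize))

#' @rdname accessors
#' @export
setGeneric("meanSUV", function(object) standardGeneric("meanSUV"))
#' @rdname accessors
#' @export
setMethod("meanSUV", "TACurve", function(object) object@meanSUV)

#' Number of voxels in a VOI
#' @param object a [VOIMask-class].
#' @return integer voxel count.
#' @export
setGeneric("voiSize", function(object) standardGeneric("voiSize"))
#' @rdname voiSize
#' @export
setMethod("voiSize", "VOIMask", function(object) sum(object@mask))

setMethod("show", "FrameSchedule", function(object) {
  cat(sprintf("FrameSchedule: %d frames, 0-%.1f min\n",
              length(object@starts),
              object@starts[length(object@starts)] +
                object@durations[length(object@durations)]))
  cat("  durations (min):", paste(object@durations, collapse = " "), "\n")
})

setMethod("show", "DynamicPETSeries", function(object) {
  d <- dim(object@values)
  cat(sprintf("DynamicPETSeries: %d x %d x %d voxels, %d frames\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel size: %.1f x %.1f x %.1f mm; SUV range %.2f-%.2f\n",
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3],
              min(object@values), max(object@values)))
})

setMethod("show", "SummedImage", function(object) {
  d <- dim(object@values)
  cat(sprintf("SummedImage (%g-%g min): %d x %d x %d voxels\n",
              object@window[1], object@window[2], d[1], d[2], d[3]))
})

setMethod("show", "VOIMask", function(object) {
  thr <- if (is.na(object@threshold)) "" else
    sprintf(" @ TBR >= %.2f", object@threshold)
  cat(sprintf("VOIMask [%s%s]: %d voxels (%.2f mL)\n", object@provenance,
              thr, sum(object@mask),
              sum(object@mask) * prod(object@voxelSize) / 1000))
})

setMethod("show", "CutoffRule", function(object) {
  op <- c(le = "<=", ge = ">=", gt = ">")[object@direction]
  cat(sprintf("CutoffRule: predict PSP when %s %s %g\n",
              object@parameter, op, object@cutoff))
})

setMethod("show", "ClassificationMetrics", function(object) {
  cat(sprintf("ClassificationMetrics (PSP positive): TP %d FP %d FN %d TN %d\n",
              object@tp, object@fp, object@fn, object@tn))
  m <- object@metrics
  cat(sprintf("  sens %.2f spec %.2f acc %.2f F1 %.2f MCC %.2f AUC %s\n",
              m["sensitivity"], m["specificity"], m["accuracy"], m["f1"],
              m["mcc"], ifelse(is.na(m["auc"]), "-",
                               sprintf("%.2f", m["auc"]))))
})

setMethod("show", "KineticClassParams", function(object) {
  cat(sprintf(
    "KineticClassParams [%s]: peak TBR %.2f +- %.2f, TTP %s, slope %.2f +- %.2f SUV/h\n",
    object@label, object@peakTbrMean, object@peakTbrSd, object@ttpMode,
    object@slopeMean, object@slopeSd))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d EP + %d PSP patients, grid %s, seed %d\n",
              object@nEP, object@nPSP,
              paste(object@gridShape, collapse = "x"), object@seed))
})
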