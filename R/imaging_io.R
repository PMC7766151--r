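#' Read and write dynamic PET series as NIfTI-1
#'
#' Volumes are stored as 4D NIfTI with float32 data and the voxel size in
#' the header pixdim; a write/read round trip preserves values to float32
#' precision and the spacing exactly. The frame schedule is not part of the
#' NIfTI header and is re-attached on read.
#'
#' @param path file path (.nii or .nii.gz).
#' @param series a [DynamicPETSeries-class].
#' @param schedule [FrameSchedule-class] attached on read; must match the
#'   4th dimension.
#' @return \code{readSeries} returns a [DynamicPETSeries-class];
#'   \code{writeSeries} returns \code{path} invisibly.
#' @export
readSeries <- function(path, schedule = frameSchedule()) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4)
    stop(sprintf("expected 4D volume (x, y, z, frame), got %dD", length(d)))
  if (d[4] != length(schedule@starts))
    stop(sprintf("file has %d frames but the schedule has %d",
                 d[4], length(schedule@starts)))
  vs <- RNifti::pixdim(img)[1:3]
  new("DynamicPETSeries", values = array(as.numeric(img), d),
      voxelSize = as.numeric(vs), schedule = schedule)
}

#' @rdname readSeries
#' @export
writeSeries <- function(series, path) {
  stopifnot(is(series, "DynamicPETSeries"))
  img <- RNifti::asNifti(series@values)
  RNifti::pixdim(img) <- c(series@voxelSize, 1)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read and write VOI masks as 0/1 NIfTI volumes
#'
#' @param path file path.
#' @param voi a [VOIMask-class].
#' @param provenance,threshold provenance metadata re-attached on read.
#' @return \code{readMask} returns a [VOIMask-class]; \code{writeMask}
#'   returns \code{path} invisibly.
#' @export
readMask <- function(path, provenance = "tumor", threshold = NA_real_) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3)
    stop(sprintf("expected 3D mask, got %dD", length(d)))
  new("VOIMask", mask = array(as.numeric(img) > 0.5, d),
      voxelSize = as.numeric(RNifti::pixdim(img)[1:3]),
      provenance = provenance, threshold = threshold)
}

#' @rdname readMask
#' @export
writeMask <- function(voi, path) {
  stopifnot(is(voi, "VOIMask"))
  img <- RNifti::asNifti(array(as.integer(voi@mask), dim(voi@mask)))
  RNifti::pixdim(img) <- voi@voxelSize
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Load the packaged 34-patient clinical cohort table
#'
#' Returns the per-patient conventional FET PET parameters (TBRmean,
#' TBRmax, TTP, slope), diagnosis (18 early tumor progression, 16
#' pseudoprogression), progression-free and overall survival with censoring
#' flags, and molecular markers, as published for the study cohort. Missing
#' values are NA; censoring flags are logical.
#'
#' @return a data.frame with 34 rows.
#' @examples
#' cohort <- loadCohortFixture()
#' table(cohort$diagnosis)
#' @export
loadCohortFixture <- function() {
  path <- system.file("extdata", "cohort_table1.csv", package = "fetrad",
                      mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$pfs_censored <- as.logical(d$pfs_censored)
  d$os_censored <- as.logical(d$os_censored)
  d
}

#' Serialize classification metrics as JSON and feature tables as CSV
#'
#' Metric reports are written as a JSON object containing the confusion
#' counts and the ten named metrics (sensitivity, specificity, PPV, NPV,
#' FNR, FPR, accuracy, F1, MCC, AUC). Feature tables are written as CSV
#' with the key columns first. Both round-trip losslessly (numbers at full
#' double precision).
#'
#' @param metrics a [ClassificationMetrics-class].
#' @param table a feature data.frame as built by [extractCohortFeatures()].
#' @param path output file.
#' @return the path, invisibly; readers return the reconstructed object.
#' @export
writeMetricsReport <- function(metrics, path) {
  stopifnot(is(metrics, "ClassificationMetrics"))
  out <- c(list(tp = metrics@tp, fp = metrics@fp, fn = metrics@fn,
                tn = metrics@tn), as.list(metrics@metrics))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname writeMetricsReport
#' @export
readMetricsReport <- function(path) {
  x <- jsonlite::read_json(path)
  m <- unlist(x[!names(x) %in% c("tp", "fp", "fn", "tn")])
  m <- vapply(m, function(v) if (is.null(v)) NA_real_ else as.numeric(v), 0)
  new("ClassificationMetrics", tp = as.numeric(x$tp), fp = as.numeric(x$fp),
      fn = as.numeric(x$fn), tn = as.numeric(x$tn), metrics = m)
}

#' @rdname writeMetricsReport
#' @export
writeFeatureTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMetricsReport
#' @export
readFeatureTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
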