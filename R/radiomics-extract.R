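# crop an image + mask to the mask bounding box with padding; padding is
# clamped at the grid so filter support never reaches mask voxels through
# an array edge on phantom-sized grids
cropToMask <- function(image, mask, pad = 8L) {
  d <- dim(mask)
  bb <- apply(which(mask, arr.ind = TRUE), 2, range)
  sub <- lapply(1:3, function(a)
    max(1L, bb[1, a] - pad):min(d[a], bb[2, a] + pad))
  list(image = image[sub[[1]], sub[[2]], sub[[3]], drop = FALSE],
       mask = mask[sub[[1]], sub[[2]], sub[[3]], drop = FALSE])
}

.TEXTURE_FAMILIES <- c("GLCM", "GLRLM", "GLSZM", "NGTDM", "GLDM")

# first-order + texture block (93 features) for one image under one mask
featureBlock93 <- function(image, mask, voxelSize, binWidth, origin) {
  fo <- firstOrderFeatures(image, mask, voxelSize, binWidth, origin)
  disc <- discretize(image, mask, binWidth, origin)
  tex <- lapply(.TEXTURE_FAMILIES, function(fam)
    textureFeatures(disc$levels, disc$ng, fam))
  names(tex) <- tolower(.TEXTURE_FAMILIES)
  out <- c(
    stats::setNames(fo, paste0("firstorder_", names(fo))),
    unlist(lapply(names(tex), function(f)
      stats::setNames(tex[[f]], paste0(f, "_", names(tex[[f]]))))))
  out
}

#' Extract the full 944-feature radiomics vector of one VOI
#'
#' Computes 107 features on the original image (18 first-order, 14 shape,
#' 24 GLCM, 16 GLRLM, 16 GLSZM, 5 NGTDM, 14 GLDM) and 93 features (all but
#' shape) on each of 9 filtered images: the Laplacian-of-Gaussian filtered
#' image and the 8 coif1 undecimated wavelet sub-bands. All images share
#' the native grid (no resampling); intensities are discretized with an
#' absolute bin width of 0.15. Feature names follow
#' \code{source_family_Feature}, e.g. \code{original_shape_MajorAxisLength}
#' or \code{wavelet_HHL_glszm_SizeZoneNonUniformity}.
#'
#' @param image 3D array or [SummedImage-class] (summed 20--40 min SUV).
#' @param mask logical array or [VOIMask-class], non-empty.
#' @param voxelSize numeric(3) mm (from the objects if omitted).
#' @param binWidth,origin absolute discretization, defaults 0.15 and 0.
#' @param logSigma LoG scale in mm, default 0.5.
#' @return named numeric of length 944.
#' @export
extractFeatures <- function(image, mask, voxelSize = NULL,
                            binWidth = 0.15, origin = 0, logSigma = 0.5) {
  if (is(image, "SummedImage")) {
    voxelSize <- voxelSize %||% image@voxelSize
    image <- image@values
  }
  if (is(mask, "VOIMask")) {
    voxelSize <- voxelSize %||% mask@voxelSize
    mask <- mask@mask
  }
  stopifnot(any(mask), length(voxelSize) == 3)
  cr <- cropToMask(image, mask)
  img <- cr$image; msk <- cr$mask

  out <- numeric(0)
  orig <- featureBlock93(img, msk, voxelSize, binWidth, origin)
  shape <- shapeFeatures(msk, voxelSize)
  out <- c(out,
           stats::setNames(orig[seq_len(18)],
                           paste0("original_", names(orig)[seq_len(18)])),
           stats::setNames(shape, paste0("original_shape_", names(shape))),
           stats::setNames(orig[-seq_len(18)],
                           paste0("original_", names(orig)[-seq_len(18)])))

  logImg <- logFilter(img, voxelSize, logSigma)
  blk <- featureBlock93(logImg, msk, voxelSize, binWidth, origin)
  out <- c(out, stats::setNames(blk, paste0("log_", names(blk))))

  wav <- waveletDecompose(img)
  for (b in names(wav)) {
    blk <- featureBlock93(wav[[b]], msk, voxelSize, binWidth, origin)
    out <- c(out, stats::setNames(blk, paste0("wavelet_", b, "_", names(blk))))
  }
  stopifnot(length(out) == 944)
  out
}

#' Radiomics feature table of a phantom cohort
#'
#' Runs the full imaging workflow on every simulated patient: summed
#' 20--40 min image, background VOI, TBR iso-contour segmentation at the
#' three augmentation thresholds (1.4, 1.6, 1.8), and [extractFeatures()]
#' per segmentation. A 34-patient cohort yields 102 rows.
#'
#' @param sim result of [simulateCohort()] (dynamic or summed output).
#' @param thresholds segmentation thresholds, default c(1.4, 1.6, 1.8).
#' @return data.frame with columns patient_id, segmentation_threshold,
#'   label and the 944 feature columns.
#' @export
extractCohortFeatures <- function(sim, thresholds = c(1.4, 1.6, 1.8)) {
  rows <- list()
  for (i in seq_along(sim$patients)) {
    pat <- sim$patients[[i]]
    summed <- if (!is.null(pat$summed)) pat$summed else sumWindow(pat$series)
    bg <- backgroundVOI(summed, pat$truth$bgCenter)
    bgMean <- voiMean(summed, bg)
    vois <- augmentSegmentations(summed, bgMean, pat$truth$searchRegion,
                                 thresholds)
    for (t in seq_along(thresholds)) {
      voi <- vois[[t]]
      if (!any(voi@mask))
        stop(sprintf("patient %d: empty segmentation at threshold %g",
                     i, thresholds[t]))
      fv <- extractFeatures(summed, voi)
      rows[[length(rows) + 1]] <- c(
        list(patient_id = sim$cohort$patient_id[i],
             segmentation_threshold = thresholds[t],
             label = sim$cohort$class[i]),
        as.list(fv))
    }
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
}
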