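#' Standard 40-min dynamic FET acquisition schedule
#'
#' The 14-frame schedule of a 0--40 min dynamic FET PET acquisition:
#' 5 frames of 1 min, 5 of 3 min and 4 of 5 min. The mid-times of the last
#' four frames (22.5, 27.5, 32.5, 37.5 min) form the grid on which
#' time-to-peak values in the late window fall.
#'
#' @return a [FrameSchedule-class] with 14 frames ending at 40 min.
#' @examples
#' sched <- frameSchedule()
#' midTimes(sched)
#' @export
frameSchedule <- function() {
  durations <- c(rep(1, 5), rep(3, 5), rep(5, 4))
  starts <- cumsum(c(0, durations[-14]))
  new("FrameSchedule", starts = starts, durations = durations,
      midTimes = starts + durations / 2)
}

#' Kinetic class parameters with the study defaults
#'
#' Default generative parameters for the two diagnostic classes. Early
#' tumor progression (EP): peak TBR 2.6 +- 0.6, early time-to-peak,
#' 20--40 min slope -0.2 +- 0.8 SUV/h, strong uptake heterogeneity
#' (amplitude 0.25, length 6 mm). Pseudoprogression (PSP): peak TBR
#' 2.0 +- 0.3, late time-to-peak, slope +0.4 +- 0.5 SUV/h, mild
#' heterogeneity (amplitude 0.08, length 12 mm).
#'
#' @param label "EP" or "PSP".
#' @param peakTbrMean,peakTbrSd peak TBR distribution.
#' @param ttpMode "early" or "late".
#' @param slopeMean,slopeSd late-window TAC slope distribution (SUV/h).
#' @param heterogeneityAmplitude,heterogeneityLength multiplicative uptake
#'   heterogeneity amplitude (fraction) and correlation length (mm).
#' @return a [KineticClassParams-class].
#' @export
kineticClassParams <- function(label = c("EP", "PSP"),
                               peakTbrMean = NULL, peakTbrSd = NULL,
                               ttpMode = NULL,
                               slopeMean = NULL, slopeSd = NULL,
                               heterogeneityAmplitude = NULL,
                               heterogeneityLength = NULL) {
  label <- match.arg(label)
  def <- if (label == "EP") {
    list(2.6, 0.6, "early", -0.2, 0.8, 0.25, 6)
  } else {
    list(2.0, 0.3, "late", 0.4, 0.5, 0.08, 12)
  }
  new("KineticClassParams", label = label,
      peakTbrMean = peakTbrMean %||% def[[1]],
      peakTbrSd = peakTbrSd %||% def[[2]],
      ttpMode = ttpMode %||% def[[3]],
      slopeMean = slopeMean %||% def[[4]],
      slopeSd = slopeSd %||% def[[5]],
      heterogeneityAmplitude = heterogeneityAmplitude %||% def[[6]],
      heterogeneityLength = heterogeneityLength %||% def[[7]])
}

#' Phantom cohort specification
#'
#' @param gridShape integer(3) voxels, default 64 x 64 x 48.
#' @param voxelSize numeric(3) mm, default 2.0 x 2.0 x 2.4.
#' @param nEP,nPSP patients per class, defaults 18 and 16.
#' @param backgroundSUV healthy-brain SUV, default 1.
#' @param lesionRadiusRange lesion semi-axis range (mm), default 12--16.
#' @param noiseSdPerMinute per-frame Gaussian noise scale (SUV*sqrt(min)),
#'   default 0.15; a frame of duration d gets voxel noise sd
#'   \code{noiseSdPerMinute/sqrt(d)}.
#' @param seed integer master seed.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(gridShape = c(64L, 64L, 48L),
                        voxelSize = c(2.0, 2.0, 2.4),
                        nEP = 18L, nPSP = 16L,
                        backgroundSUV = 1.0,
                        lesionRadiusRange = c(12, 16),
                        noiseSdPerMinute = 0.15,
                        seed = 1L) {
  new("PhantomSpec", gridShape = as.integer(gridShape),
      voxelSize = as.numeric(voxelSize), nEP = as.integer(nEP),
      nPSP = as.integer(nPSP), backgroundSUV = backgroundSUV,
      lesionRadiusRange = as.numeric(lesionRadiusRange),
      noiseSdPerMinute = noiseSdPerMinute, seed = as.integer(seed))
}

#' Deterministic per-patient seed derivation
#'
#' Hashes the master seed and the patient index into a reproducible
#' per-patient seed so cohorts are extensible without perturbing earlier
#' patients. Stays below 2^31.
#'
#' @param seed master seed (integer).
#' @param index patient index (1-based).
#' @return integer seed in [1, 2^31 - 2].
#' @export
patientSeed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 104729) %%
               2147483647) + 1L
}

# nominal lesion / background geometry (mm, world = 0-based index * spacing)
phantomGeometry <- function(spec) {
  ext <- spec@gridShape * spec@voxelSize
  lesion <- c(0.72 * ext[1], 0.5 * ext[2], 0.5 * ext[3])
  bg <- c(ext[1] - lesion[1], lesion[2], lesion[3])  # mirrored across midplane
  list(lesionCenter = lesion, bgCenter = bg, extent = ext)
}

# world coordinates of voxel centers along each axis
axisCoords <- function(gridShape, voxelSize)
  lapply(1:3, function(a) (seq_len(gridShape[a]) - 1) * voxelSize[a])

# smooth multiplicative heterogeneity field on a bounding box: Gaussian
# smoothed white noise, scaled to max |.| = 1 over the lesion core
smoothNoiseField <- function(dims, voxelSize, lengthMm) {
  z <- array(stats::rnorm(prod(dims)), dims)
  for (a in 1:3) {
    sig <- lengthMm / voxelSize[a] / 2   # correlation length ~ 2 sigma
    r <- max(1L, ceiling(3 * sig))
    k <- exp(-0.5 * ((-r:r) / sig)^2)
    k <- k / sum(k)
    z <- convolveAxis(z, k, a, boundary = "reflect")
  }
  z
}

#' Simulate one dynamic FET PET patient
#'
#' Generates a lesion as a smoothly tapered ellipsoid in one hemisphere of
#' the grid, calibrated so that in the noise-free summed 20--40 min image
#' the mean of the 16 mm sphere centered on the hottest voxel - the
#' quantity the conventional workflow reports as TBRmax - equals the drawn
#' peak TBR times the background SUV. The lesion carries a multiplicative
#' smooth random uptake field with the class amplitude and correlation
#' length, windowed toward the lesion core. Time dependence is a
#' piecewise-linear multiplicative profile: "early" kinetics peak in frames
#' 8--10 and then follow the drawn late-window slope; "late" kinetics
#' increase through the final frame. Per-frame voxel noise is zero-mean
#' Gaussian with sd \code{noiseSdPerMinute/sqrt(frame duration)}, clamped
#' at SUV 0.
#'
#' @param spec a [PhantomSpec-class].
#' @param kinetics a [KineticClassParams-class].
#' @param patientSeed integer seed for this patient.
#' @param lesionCenter optional lesion center (world mm) overriding the
#'   default hemisphere placement with jitter.
#' @param output "dynamic" for the full 4D series (default) or "summed" for
#'   only the 20--40 min summed image with distribution-equivalent noise
#'   (sd scaled by 1/sqrt(window length)); the summed route is exact for
#'   static parameters because Gaussian noise averages linearly.
#' @return a list with elements \code{series} ([DynamicPETSeries-class],
#'   dynamic output) or \code{summed} ([SummedImage-class]), and
#'   \code{truth}: lesion mask ([VOIMask-class]-like logical array), class
#'   label, drawn peak TBR, realized slope (SUV/h), time-to-peak mode,
#'   lesion/background centers (mm), search-region hemisphere mask, seed.
#' @export
simulatePatient <- function(spec, kinetics, patientSeed,
                            output = c("dynamic", "summed"),
                            lesionCenter = NULL) {
  output <- match.arg(output)
  stopifnot(is(spec, "PhantomSpec"), is(kinetics, "KineticClassParams"))
  validObject(spec); validObject(kinetics)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(patientSeed)

  geom <- phantomGeometry(spec)
  dims <- spec@gridShape
  vs <- spec@voxelSize
  bgSUV <- spec@backgroundSUV

  # draws: peak TBR (truncated at 1.85 so every lesion stays segmentable at
  # the highest augmentation threshold 1.8), semi-axes, center, slope
  peakTbr <- max(1.85, stats::rnorm(1, kinetics@peakTbrMean, kinetics@peakTbrSd))
  semi <- stats::runif(3, spec@lesionRadiusRange[1], spec@lesionRadiusRange[2])
  center <- lesionCenter %||% (geom$lesionCenter + stats::runif(3, -4, 4))
  slope <- stats::rnorm(1, kinetics@slopeMean, kinetics@slopeSd)
  if (kinetics@ttpMode == "late") slope <- max(slope, 0.05)

  # geometry conflict: lesion must not reach the background sphere
  if (sqrt(sum((center - geom$bgCenter)^2)) < 15 + max(semi) + 2)
    stop("geometry conflict: lesion overlaps the background sphere region")

  co <- axisCoords(dims, vs)
  # normalized ellipsoidal radius e(x), vectorized by outer sums
  e2 <- outer(outer(((co[[1]] - center[1]) / semi[1])^2,
                    ((co[[2]] - center[2]) / semi[2])^2, "+"),
              ((co[[3]] - center[3]) / semi[3])^2, "+")
  e <- sqrt(e2)
  # flat plateau with a raised-cosine rolloff over the outer 2 mm, so the
  # 16 mm peak sphere around a near-central hot voxel samples plateau
  # uptake and the sphere mean tracks the drawn peak TBR
  w <- 2 / min(semi)
  base <- array(0, dims)
  inside <- e <= 1
  roll <- e > (1 - w) & inside
  # parabolic dome (uptake declines toward the rim, as in real lesions,
  # keeping the VOI-mean TBR below the peak-sphere TBR) with a
  # raised-cosine rim rolloff
  base[inside] <- 1 - 0.35 * e2[inside]
  base[roll] <- base[roll] *
    0.5 * (1 + cos(pi * (e[roll] - (1 - w)) / w))

  # multiplicative heterogeneity, windowed toward the lesion core so the
  # hottest voxel lands well inside the plateau
  if (kinetics@heterogeneityAmplitude > 0) {
    bb <- apply(which(inside, arr.ind = TRUE), 2, range)
    sub <- lapply(1:3, function(a) bb[1, a]:bb[2, a])
    f <- smoothNoiseField(vapply(sub, length, 1L), vs,
                          kinetics@heterogeneityLength)
    f <- f / stats::sd(f)   # amplitude = sd as a fraction of lesion uptake
    het <- array(0, dims)
    het[sub[[1]], sub[[2]], sub[[3]]] <- f
    base <- pmax(base * (1 + kinetics@heterogeneityAmplitude * het * base), 0)
  }
  lnorm <- base / max(base)
  peakVoxel <- which.max(lnorm)
  # calibrate the uptake excess so the 16 mm sphere mean at the hottest
  # voxel - i.e. the TBRmax the conventional workflow extracts - equals
  # the drawn peak TBR exactly in the noise-free summed image
  pv <- arrayInd(peakVoxel, dims)
  sph <- sphereMask(dims, vs, (as.numeric(pv) - 1) * vs, 8)
  sphereGain <- mean(lnorm[sph])

  # time profile p(t) at frame mid-times; duration-weighted mean over the
  # 20-40 min window is 1 by construction, so the summed image at the
  # hottest voxel equals bgSUV * peakTbr
  sched <- frameSchedule()
  mt <- sched@midTimes
  late <- sched@starts >= 20
  excess <- peakTbr - 1
  p <- numeric(14)
  cPerMin <- slope / 60 / (bgSUV * excess)   # profile slope per minute
  p[late] <- 1 + cPerMin * (mt[late] - 30)
  if (kinetics@ttpMode == "late") {
    # monotone rise from 0 to the start of the late window
    p[!late] <- p[which(late)[1]] * (mt[!late] / 20)^0.7 * 0.95
  } else {
    fPeak <- sample(8:10, 1)
    pPeak <- 1.15 * max(p[late], 1)
    p[1:fPeak] <- pPeak * (mt[1:fPeak] / mt[fPeak])^0.7
    if (fPeak < 10) {
      after <- (fPeak + 1):10
      # linear descent from the early peak into the late window
      p[after] <- pPeak + (p[11] - pPeak) * (mt[after] - mt[fPeak]) /
        (mt[11] - mt[fPeak])
    }
  }
  p <- pmax(p, 0)

  truthMask <- base > 0.5
  searchRegion <- array(FALSE, dims)
  searchRegion[co[[1]] > geom$extent[1] / 2, , ] <- TRUE
  truth <- list(label = kinetics@label, peakTbr = peakTbr, slope = slope,
                ttpMode = kinetics@ttpMode, lesionMask = truthMask,
                lesionCenter = center, bgCenter = geom$bgCenter,
                peakVoxel = peakVoxel, searchRegion = searchRegion,
                seed = patientSeed)

  excessEff <- excess / sphereGain
  if (output == "summed") {
    vals <- bgSUV * (1 + excessEff * lnorm)   # window mean of p is 1
    if (spec@noiseSdPerMinute > 0) {
      winLen <- 40 - 20
      vals <- vals + stats::rnorm(length(vals),
                                  sd = spec@noiseSdPerMinute / sqrt(winLen))
      vals <- pmax(vals, 0)
    }
    summed <- new("SummedImage", values = array(vals, dims), voxelSize = vs,
                  window = c(20, 40))
    return(list(summed = summed, truth = truth))
  }

  vals <- array(0, c(dims, 14L))
  for (f in 1:14) {
    frame <- bgSUV * (1 + excessEff * lnorm * p[f])
    if (spec@noiseSdPerMinute > 0)
      frame <- frame + stats::rnorm(length(frame),
                                    sd = spec@noiseSdPerMinute /
                                      sqrt(sched@durations[f]))
    vals[, , , f] <- frame
  }
  vals <- pmax(vals, 0)
  series <- new("DynamicPETSeries", values = vals, voxelSize = vs,
                schedule = sched)
  list(series = series, truth = truth)
}

#' Simulate a labelled phantom cohort
#'
#' Generates \code{nEP + nPSP} patients with per-patient seeds derived
#' deterministically from the master seed via [patientSeed()], EP patients
#' first.
#'
#' @param spec a [PhantomSpec-class].
#' @param kineticsEP,kineticsPSP class parameters; study defaults if NULL.
#' @param output "dynamic" or "summed", see [simulatePatient()].
#' @return a list with \code{patients} (list of [simulatePatient()] results)
#'   and \code{cohort}, a data.frame with patient_id, class label, drawn
#'   peak TBR and seed.
#' @export
simulateCohort <- function(spec, kineticsEP = NULL, kineticsPSP = NULL,
                           output = c("dynamic", "summed")) {
  output <- match.arg(output)
  kineticsEP <- kineticsEP %||% kineticClassParams("EP")
  kineticsPSP <- kineticsPSP %||% kineticClassParams("PSP")
  n <- spec@nEP + spec@nPSP
  labels <- c(rep("EP", spec@nEP), rep("PSP", spec@nPSP))
  patients <- vector("list", n)
  for (i in seq_len(n)) {
    k <- if (labels[i] == "EP") kineticsEP else kineticsPSP
    patients[[i]] <- simulatePatient(spec, k, patientSeed(spec@seed, i),
                                     output = output)
  }
  cohort <- data.frame(
    patient_id = seq_len(n),
    class = labels,
    true_peak_tbr = vapply(patients, function(p) p$truth$peakTbr, 0),
    seed = vapply(patients, function(p) p$truth$seed, 0),
    stringsAsFactors = FALSE)
  list(patients = patients, cohort = cohort)
}
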