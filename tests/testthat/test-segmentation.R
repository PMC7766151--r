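constSeries <- function(value, dims = c(20, 20, 16)) {
  new("DynamicPETSeries", values = array(value, c(dims, 14)),
      voxelSize = c(2, 2, 2.4), schedule = frameSchedule())
}

summedOf <- function(arr, vs = c(2, 2, 2.4))
  new("SummedImage", values = arr, voxelSize = vs, window = c(20, 40))

test_that("summed image is the duration-weighted mean of the late frames", {
  s <- constSeries(3.7)
  expect_equal(unique(as.numeric(suvValues(sumWindow(s)))), 3.7)

  v <- array(0, c(4, 4, 4, 14))
  for (f in 11:14) v[, , , f] <- f - 10   # frames 11-14 hold 1, 2, 3, 4
  s2 <- new("DynamicPETSeries", values = v, voxelSize = c(2, 2, 2.4),
            schedule = frameSchedule())
  sm <- sumWindow(s2)
  expect_equal(unique(as.numeric(suvValues(sm))), 2.5)   # equal durations
  # the default window covers exactly the four 5-min frames
  sched <- frameSchedule()
  expect_equal(sum(sched@starts >= 20), 4)
  expect_error(sumWindow(s2, start = 21, end = 40), "frame boundaries")
})

test_that("background sphere has the nominal 14 mL volume on the PET grid", {
  img <- summedOf(array(1.3, c(40, 40, 30)))
  voi <- backgroundVOI(img, center = c(40, 40, 36))
  volML <- voiSize(voi) * voxelVolume(voi) / 1000
  expect_gt(volML, 13.2)
  expect_lt(volML, 15.1)
  expect_equal(voiMean(img, voi), 1.3)
  expect_error(backgroundVOI(img, center = c(4, 40, 36)), "clipped")
})

test_that("autocontour keeps supra-threshold voxels of the largest component", {
  img <- array(1, c(12, 12, 12))
  expect_false(any(maskArray(autocontour(summedOf(img), bgMean = 1))))

  # a 3x3x3 block exactly at 1.6 x background is included (inclusive rule)
  img2 <- array(1, c(12, 12, 12))
  img2[5:7, 5:7, 5:7] <- 1.6
  voi <- autocontour(summedOf(img2), bgMean = 1)
  expect_equal(voiSize(voi), 27)

  # two disjoint blobs: only the larger 26-connected component survives
  img3 <- array(1, c(14, 14, 6))
  img3[2:6, 2:3, 2] <- 2      # 10 voxels
  img3[10:13, 10, 2] <- 2     # 4 voxels
  voi3 <- autocontour(summedOf(img3), bgMean = 1)
  expect_equal(voiSize(voi3), 10)
  expect_true(all(which(maskArray(voi3), arr.ind = TRUE)[, 1] <= 6))
})

test_that("threshold augmentation yields three nested masks", {
  withr::with_seed(7, {
    for (rep in 1:25) {
      base <- array(stats::runif(10 * 10 * 8, 0.5, 1.5), c(10, 10, 8))
      bump <- array(0, c(10, 10, 8))
      bump[3:7, 3:7, 3:6] <- stats::runif(1, 0.5, 2.5)
      img <- summedOf(base + bump)
      vois <- augmentSegmentations(img, bgMean = 1)
      expect_length(vois, 3)
      m14 <- maskArray(vois[["tbr_1.4"]])
      m16 <- maskArray(vois[["tbr_1.6"]])
      m18 <- maskArray(vois[["tbr_1.8"]])
      expect_true(all(m18 <= m16))
      expect_true(all(m16 <= m14))
    }
  })
})

test_that("peak sphere sits at the hottest voxel with the nominal 2 mL volume", {
  img <- array(1, c(24, 24, 20))
  img[12, 12, 10] <- 4
  sm <- summedOf(img)
  within <- new("VOIMask", mask = img > 1, voxelSize = c(2, 2, 2.4),
                provenance = "tumor", threshold = 1.6)
  sph <- peakSphere(sm, within)
  volML <- voiSize(sph) * voxelVolume(sph) / 1000
  expect_equal(volML, 2.145, tolerance = 0.1)
  # sphere is centered on the hot voxel
  ctr <- arrayInd(which.max(img), dim(img))
  expect_true(maskArray(sph)[ctr])

  # argmax ties break toward the lowest linear index
  img2 <- array(2, c(10, 10, 10))
  within2 <- new("VOIMask", mask = array(TRUE, c(10, 10, 10)),
                 voxelSize = c(2, 2, 2.4), provenance = "tumor",
                 threshold = 1.6)
  sph2 <- peakSphere(summedOf(img2), within2)
  expect_true(maskArray(sph2)[1, 1, 1])

  emptyVoi <- new("VOIMask", mask = array(FALSE, c(10, 10, 10)),
                  voxelSize = c(2, 2, 2.4), provenance = "tumor",
                  threshold = 1.6)
  expect_error(peakSphere(summedOf(img2), emptyVoi), "no tumor voxels")
})

test_that("tumor VOI voxels all exceed the threshold and avoid the background VOI", {
  spec <- phantomSpec(seed = 21L)
  pat <- simulatePatient(spec, kineticClassParams("EP"), 42L,
                         output = "summed")
  bg <- backgroundVOI(pat$summed, pat$truth$bgCenter)
  bgMean <- voiMean(pat$summed, bg)
  voi <- autocontour(pat$summed, bgMean, 1.6, pat$truth$searchRegion)
  expect_true(all(suvValues(pat$summed)[maskArray(voi)] / bgMean >= 1.6))
  expect_gte(tbrMean(pat$summed, voi, bg), 1.6)
  expect_false(any(maskArray(voi) & maskArray(bg)))
})
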