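test_that("absolute discretization follows the floor rule", {
  img <- array(c(0.10, 0.16, 0.31), c(3, 1, 1))
  msk <- array(TRUE, c(3, 1, 1))
  d <- discretize(img, msk, binWidth = 0.15)
  expect_equal(as.integer(d$levels), c(1L, 2L, 3L))
  expect_equal(d$ng, 3L)

  dOne <- discretize(array(c(0.01, 0.05, 0.1), c(3, 1, 1)), msk, 0.15)
  expect_equal(dOne$ng, 1L)
  # degenerate single-level texture matrices stay defined
  for (fam in c("GLCM", "GLRLM", "GLSZM", "NGTDM", "GLDM"))
    expect_true(all(is.finite(textureFeatures(dOne$levels, dOne$ng, fam))))
})

test_that("doubling the bin width cannot increase the gray-level count", {
  withr::with_seed(4, {
    for (i in 1:20) {
      img <- array(stats::runif(60, 0, 5), c(5, 4, 3))
      msk <- array(stats::runif(60) > 0.3, c(5, 4, 3))
      if (!any(msk)) next
      n1 <- discretize(img, msk, 0.15)$ng
      n2 <- discretize(img, msk, 0.30)$ng
      expect_lte(n2, n1)
    }
  })
})

test_that("first-order features match hand-computed values", {
  img <- array(c(1, 2, 3), c(3, 1, 1))
  msk <- array(TRUE, c(3, 1, 1))
  fo <- firstOrderFeatures(img, msk, c(1, 1, 1))
  expect_length(fo, 18)
  expect_equal(fo[["Energy"]], 14)
  expect_equal(fo[["Maximum"]], 3)
  expect_equal(fo[["Mean"]], 2)

  const <- firstOrderFeatures(array(2.5, c(4, 3, 2)), array(TRUE, c(4, 3, 2)),
                              c(2, 2, 2.4))
  expect_equal(const[["Variance"]], 0)
  expect_equal(const[["Uniformity"]], 1)
  expect_equal(const[["Skewness"]], 0)
})

test_that("first-order features ignore mask voxel ordering", {
  withr::with_seed(9, {
    img <- array(stats::runif(8 * 7 * 6, 0, 4), c(8, 7, 6))
    msk <- array(stats::runif(8 * 7 * 6) > 0.5, c(8, 7, 6))
    a <- firstOrderFeatures(img, msk, c(2, 2, 2.4))
    perm <- aperm(img, c(2, 1, 3))
    b <- firstOrderFeatures(perm, aperm(msk, c(2, 1, 3)), c(2, 2, 2.4))
    expect_equal(a, b)
  })
})

test_that("shape features follow the stated conventions", {
  # 3 collinear voxels spaced 2 mm: sample variance 4, major axis 8 mm
  mk <- array(FALSE, c(5, 3, 3)); mk[1:3, 2, 2] <- TRUE
  sf <- shapeFeatures(mk, c(2, 1, 1))
  expect_length(sf, 14)
  expect_equal(sf[["MajorAxisLength"]], 8)

  # cubic mask on a cubic grid: all three axes equal
  cube <- array(FALSE, c(8, 8, 8)); cube[3:6, 3:6, 3:6] <- TRUE
  sc <- shapeFeatures(cube, c(2, 2, 2))
  expect_equal(sc[["MajorAxisLength"]], sc[["MinorAxisLength"]],
               tolerance = 1e-9)
  expect_equal(sc[["MinorAxisLength"]], sc[["LeastAxisLength"]],
               tolerance = 1e-9)
  expect_equal(sc[["VoxelVolume"]], 64 * 8)

  single <- array(FALSE, c(3, 3, 3)); single[2, 2, 2] <- TRUE
  expect_warning(ss <- shapeFeatures(single, c(2, 2, 2.4)), "single-voxel")
  expect_equal(ss[["MajorAxisLength"]], 0)
})

test_that("LoG filter reproduces its analytic kernel and kills constants", {
  expect_lt(max(abs(logFilter(array(3.3, c(8, 8, 8)), c(2, 2, 2.4)))), 1e-10)

  img <- array(0, c(15, 15, 15)); img[8, 8, 8] <- 1
  fl <- logFilter(img, c(2, 2, 2.4), sigma = 0.5)
  K <- oracleLoGKernel(0.5, c(2, 2, 2.4))
  r <- (dim(K) - 1) / 2
  sub <- fl[(8 - r[1]):(8 + r[1]), (8 - r[2]):(8 + r[2]),
            (8 - r[3]):(8 + r[3])]
  expect_lt(max(abs(sub - K)), 1e-6)
})

test_that("wavelet decomposition yields 8 grid-preserving coif1 sub-bands", {
  w <- waveletDecompose(array(2, c(8, 8, 8)))
  expect_length(w, 8)
  expect_identical(names(w),
                   c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH"))
  expect_equal(unique(round(as.numeric(w$LLL), 10)),
               round(2 * sum(fetrad:::COIF1_LO)^3, 10))
  for (b in names(w)[-1]) expect_lt(max(abs(w[[b]])), 1e-10)
  expect_equal(dim(w$HHH), c(8, 8, 8))

  # a profile varying only along x puts energy only into bands that
  # high-pass x (coif1 has two vanishing moments, so use a quadratic)
  ramp <- array(rep((1:12)^2 / 12, times = 12 * 10), c(12, 12, 10))
  wr <- waveletDecompose(ramp)
  inner <- function(a) a[4:9, 4:9, 4:7]   # avoid the periodic wrap
  expect_gt(sum(inner(wr$HLL)^2), 1e-4)
  expect_lt(sum(inner(wr$LLH)^2), 1e-10)
  expect_lt(sum(inner(wr$LHL)^2), 1e-10)
})

test_that("the full feature vector has the documented 944-name structure", {
  withr::with_seed(5, {
    img <- array(stats::runif(14 * 13 * 12, 0.5, 3), c(14, 13, 12))
    msk <- array(FALSE, c(14, 13, 12)); msk[5:10, 5:9, 5:8] <- TRUE
    fv <- extractFeatures(img, msk, c(2, 2, 2.4))
    expect_length(fv, 944)
    expect_false(any(duplicated(names(fv))))
    expect_equal(sum(startsWith(names(fv), "original_")), 107)
    expect_equal(sum(startsWith(names(fv), "log_")), 93)
    expect_equal(sum(startsWith(names(fv), "wavelet_")), 744)
    expect_equal(sum(grepl("_shape_", names(fv))), 14)
    expect_true("original_shape_MajorAxisLength" %in% names(fv))
    expect_true("original_firstorder_Energy" %in% names(fv))
    expect_true("original_glszm_SizeZoneNonUniformity" %in% names(fv))
  })
})

test_that("whole-voxel translation leaves all 944 features unchanged", {
  withr::with_seed(6, {
    d <- c(32, 30, 28)
    img <- array(stats::runif(prod(d), 0.5, 3), d)
    msk <- array(FALSE, d); msk[12:16, 12:15, 12:15] <- TRUE
    sh <- c(3, 2, 1)
    shifted <- array(0.7, d)
    shifted[(sh[1] + 1):d[1], (sh[2] + 1):d[2], (sh[3] + 1):d[3]] <-
      img[1:(d[1] - sh[1]), 1:(d[2] - sh[2]), 1:(d[3] - sh[3])]
    mskShift <- array(FALSE, d)
    mskShift[12:16 + sh[1], 12:15 + sh[2], 12:15 + sh[3]] <- TRUE
    a <- extractFeatures(img, msk, c(2, 2, 2.4))
    b <- extractFeatures(shifted, mskShift, c(2, 2, 2.4))
    expect_equal(a, b, tolerance = 1e-12)
  })
})
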