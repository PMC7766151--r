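test_that("texture matrices equal brute-force enumeration on random volumes", {
  withr::with_seed(11, {
    for (i in 1:60) {
      lev <- randomLevelArray()
      ng <- max(lev)
      gl <- textureMatrix(lev, ng, "GLCM")
      or <- oracleGLCM(lev, ng)
      for (k in 1:13) expect_equal(unname(gl[[k]]), or[[k]])
      rl <- textureMatrix(lev, ng, "GLRLM")
      orl <- oracleGLRLM(lev, ng)
      for (k in 1:13)
        expect_equal(unname(rl[[k]][, seq_len(ncol(orl[[k]])), drop = FALSE]),
                     orl[[k]])
      expect_equal(unname(textureMatrix(lev, ng, "GLSZM")),
                   oracleGLSZM(lev, ng))
      expect_equal(unname(textureMatrix(lev, ng, "GLDM")),
                   oracleGLDM(lev, ng))
      expect_equal(unname(textureMatrix(lev, ng, "NGTDM")),
                   oracleNGTDM(lev, ng), tolerance = 1e-12)
    }
  })
})

test_that("worked size-zone example: zones {1,1},{2},{3} give SZN 5/3", {
  lev <- array(c(1L, 1L, 2L, 3L), c(4, 1, 1))
  f <- textureFeatures(lev, 3, "GLSZM")
  expect_equal(f[["SizeZoneNonUniformity"]], 5 / 3)
  expect_length(f, 16)
})

test_that("constant VOIs give the degenerate texture limits", {
  lev <- array(1L, c(3, 3, 3))
  glcm <- textureFeatures(lev, 1, "GLCM")
  expect_equal(glcm[["Contrast"]], 0)
  expect_equal(glcm[["Correlation"]], 1)
  expect_equal(glcm[["JointEnergy"]], 1)
  # single gray level: per-direction GLN reduces to the run count
  glrlm <- textureFeatures(lev, 1, "GLRLM")
  expect_equal(glrlm[["GrayLevelNonUniformity"]],
               mean(vapply(textureMatrix(lev, 1, "GLRLM"), sum, 0)))
  glszm <- textureFeatures(lev, 1, "GLSZM")
  expect_equal(glszm[["ZonePercentage"]], 1 / 27)   # one 27-voxel zone
  expect_equal(textureFeatures(lev, 1, "NGTDM")[["Contrast"]], 0)
})

test_that("selected texture features match naive formulary evaluation", {
  withr::with_seed(12, {
    for (i in 1:20) {
      lev <- randomLevelArray()
      ng <- max(lev)
      np <- sum(lev > 0)

      # GLSZM small-area emphasis and zone percentage, by direct loops
      zm <- oracleGLSZM(lev, ng)
      nz <- sum(zm)
      sae <- 0
      for (g in seq_len(nrow(zm))) for (s in seq_len(ncol(zm)))
        sae <- sae + zm[g, s] / s^2
      f <- textureFeatures(lev, ng, "GLSZM")
      expect_equal(f[["SmallAreaEmphasis"]], sae / nz, tolerance = 1e-9)
      expect_equal(f[["ZonePercentage"]], nz / np, tolerance = 1e-9)

      # GLDM large-dependence emphasis
      dm <- oracleGLDM(lev, ng)
      lde <- 0
      for (g in seq_len(nrow(dm))) for (j in seq_len(ncol(dm)))
        lde <- lde + dm[g, j] * j^2
      expect_equal(textureFeatures(lev, ng, "GLDM")[["LargeDependenceEmphasis"]],
                   lde / sum(dm), tolerance = 1e-9)

      # GLCM contrast averaged over directions, from the oracle matrices
      ms <- oracleGLCM(lev, ng)
      vals <- c()
      for (m in ms) {
        if (sum(m) == 0) next
        p <- m / sum(m)
        con <- 0
        for (a in seq_len(ng)) for (b in seq_len(ng))
          con <- con + (a - b)^2 * p[a, b]
        vals <- c(vals, con)
      }
      expect_equal(textureFeatures(lev, ng, "GLCM")[["Contrast"]],
                   mean(vals), tolerance = 1e-9)

      # GLRLM short-run emphasis averaged over directions
      rs <- oracleGLRLM(lev, ng)
      vals <- c()
      for (m in rs) {
        if (sum(m) == 0) next
        sre <- 0
        for (a in seq_len(nrow(m))) for (l in seq_len(ncol(m)))
          sre <- sre + m[a, l] / l^2
        vals <- c(vals, sre / sum(m))
      }
      expect_equal(textureFeatures(lev, ng, "GLRLM")[["ShortRunEmphasis"]],
                   mean(vals), tolerance = 1e-9)

      # NGTDM coarseness from the oracle s_i / n_i table
      nm <- oracleNGTDM(lev, ng)
      den <- sum(nm[, 1] / np * nm[, 2])
      coarse <- if (den > 0) min(1 / den, 1e6) else 1e6
      expect_equal(textureFeatures(lev, ng, "NGTDM")[["Coarseness"]],
                   coarse, tolerance = 1e-9)
    }
  })
})

test_that("texture families report their documented feature counts", {
  lev <- array(sample(1:4, 60, replace = TRUE), c(5, 4, 3))
  storage.mode(lev) <- "integer"
  expect_length(textureFeatures(lev, 4, "GLCM"), 24)
  expect_length(textureFeatures(lev, 4, "GLRLM"), 16)
  expect_length(textureFeatures(lev, 4, "GLSZM"), 16)
  expect_length(textureFeatures(lev, 4, "NGTDM"), 5)
  expect_length(textureFeatures(lev, 4, "GLDM"), 14)
})
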