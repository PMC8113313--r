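constVol <- function(value = 100, n = 6, spacing = c(1, 1, 1)) {
  img <- array(value, dim = c(n, n, n))
  mask <- array(FALSE, dim = c(n, n, n))
  mask[2:(n - 1), 2:(n - 1), 2:(n - 1)] <- TRUE
  volumeWithMask(img, mask, spacing)
}

test_that("discretization bins equal-width over the in-mask range", {
  img <- array(0, dim = c(32, 1, 1))
  img[, 1, 1] <- 0:31
  vol <- volumeWithMask(img, array(TRUE, dim = c(32, 1, 1)))
  q <- discretizeVolume(vol, 32)
  expect_equal(q@levels[, 1, 1], 1:32)

  qc <- discretizeVolume(constVol(), 32)
  expect_identical(unique(qc@levels[!is.na(qc@levels)]), 1L)
  expect_identical(qc@gEffective, 1L)

  withr::with_seed(8, {
    u <- array(runif(4096), dim = c(16, 16, 16))
    vu <- volumeWithMask(u, array(TRUE, dim = c(16, 16, 16)))
    occ <- tabulate(discretizeVolume(vu, 8)@levels, nbins = 8)
    expected <- 4096 / 8
    bound <- 3 * sqrt(4096 * (1 / 8) * (7 / 8))
    expect_true(all(abs(occ - expected) <= bound))
  })
})

test_that("first-order statistics match hand computations", {
  fo <- firstOrderFeatures(constVol(value = 7))
  n <- sum(constVol()@mask)
  expect_equal(unname(fo["variance"]), 0)
  expect_equal(unname(fo["entropy"]), 0)
  expect_equal(unname(fo["energy"]), n * 49)
  expect_equal(unname(fo["uniformity"]), 1)
  expect_equal(unname(fo["skewness"]), 0)

  img <- array(0, dim = c(4, 1, 1)); img[, 1, 1] <- 1:4
  vol <- volumeWithMask(img, array(TRUE, dim = c(4, 1, 1)))
  fo4 <- firstOrderFeatures(vol)
  expect_equal(unname(fo4["mean"]), 2.5)
  expect_equal(unname(fo4["variance"]), 1.25)  # population convention
  expect_equal(unname(fo4["range"]), 3)

  withr::with_seed(2, {
    img <- array(rnorm(125)^3, dim = c(5, 5, 5))
    v1 <- volumeWithMask(img, array(TRUE, dim = c(5, 5, 5)))
    v2 <- volumeWithMask(-img, array(TRUE, dim = c(5, 5, 5)))
    f1 <- firstOrderFeatures(v1); f2 <- firstOrderFeatures(v2)
    expect_equal(unname(f1["skewness"]), -unname(f2["skewness"]))
    expect_equal(unname(f1["kurtosis"]), unname(f2["kurtosis"]))
  })
})

test_that("shape features match analytic solids", {
  img <- array(1, dim = c(3, 3, 3))
  mask <- array(FALSE, dim = c(3, 3, 3)); mask[2, 2, 2] <- TRUE
  single <- shapeFeatures(volumeWithMask(img, mask))
  expect_equal(unname(single["volume"]), 1)
  expect_equal(unname(single["surface_area"]), 6)
  expect_equal(unname(single["max_diameter"]), 0)

  img <- array(1, dim = c(12, 12, 12))
  mask <- array(FALSE, dim = c(12, 12, 12))
  mask[2:11, 2:11, 2:11] <- TRUE
  cube <- shapeFeatures(volumeWithMask(img, mask))
  expect_equal(unname(cube["volume"]), 1000)
  expect_equal(unname(cube["surface_area"]), 600)

  ball <- generatePhantom(c(26, 26, 26), shapeKind = "sphere", radius = 9,
                          seed = 1)
  egg <- generatePhantom(c(40, 16, 16), shapeKind = "ellipsoid",
                         radius = c(18, 4.6, 4.6), seed = 1)
  expect_gt(shapeFeatures(ball)["sphericity"],
            shapeFeatures(egg)["sphericity"])
})

test_that("LoG and Haar filters behave on constants and impulses", {
  cv <- constVol(value = 50, n = 8)
  lg <- filterImage(cv, "log", sigmaMM = 1)
  expect_lt(max(abs(lg@image[cv@mask])), 1e-8)

  lll <- filterImage(cv, "wavelet", subband = "LLL")
  expect_lt(diff(range(lll@image[cv@mask])), 1e-8)
  for (code in c("HLL", "LHL", "LLH", "HHH")) {
    hb <- filterImage(cv, "wavelet", subband = code)
    expect_lt(max(abs(hb@image[cv@mask])), 1e-8)
  }
  expect_error(filterImage(cv, "wavelet", subband = "LLX"), "subband")

  # impulse: LoG peak magnitude decreases with scale
  img <- array(0, dim = c(15, 15, 15)); img[8, 8, 8] <- 100
  vol <- volumeWithMask(img, array(TRUE, dim = c(15, 15, 15)))
  peaks <- vapply(c(1, 2, 3), function(s)
    max(abs(filterImage(vol, "log", sigmaMM = s)@image)), numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("texture features satisfy their closed-form degenerate cases", {
  q <- discretizeVolume(constVol(n = 5), 32)
  glcm <- textureFeatures(q, "glcm")
  expect_equal(unname(glcm["contrast"]), 0)
  expect_equal(unname(glcm["energy"]), 1)

  # constant 3x1x1 strip: one full-length run per direction
  img <- array(5, dim = c(4, 1, 1))
  vol <- volumeWithMask(img, array(TRUE, dim = c(4, 1, 1)))
  qs <- discretizeVolume(vol, 8)
  glrlm <- textureFeatures(qs, "glrlm")
  expect_gt(unname(glrlm["run_long_emphasis"]), 1)

  # 1D strip [1,1,2,2]: runs {(1,2),(2,2)} along +x; run percentage 0.5
  img <- array(0, dim = c(4, 1, 1)); img[, 1, 1] <- c(1, 1, 2, 2)
  vol <- volumeWithMask(img, array(TRUE, dim = c(4, 1, 1)))
  lv <- discretizeVolume(vol, 2)@levels
  counts <- radphen:::.glrlmCounts(lv, c(1L, 0L, 0L), 2L)
  expect_equal(counts[1, 2], 1L)
  expect_equal(counts[2, 2], 1L)
  expect_equal(sum(counts), 2L)
  expect_equal(sum(counts) / 4, 0.5)
})

test_that("texture matrices equal exhaustive enumeration on tiny volumes", {
  withr::with_seed(11, {
    for (rep in 1:3) {
      img <- array(sample(1:4, 64, replace = TRUE), dim = c(4, 4, 4))
      mask <- array(runif(64) < 0.8, dim = c(4, 4, 4))
      mask[2, 2, 2] <- TRUE
      lv <- array(NA_integer_, dim = c(4, 4, 4))
      lv[mask] <- img[mask]
      dirs <- radphen:::.directions13()
      for (r in seq_len(nrow(dirs))) {
        expect_identical(radphen:::.glcmCounts(lv, dirs[r, ], 4L),
                         glcmBrute(lv, dirs[r, ], 4L))
        a <- radphen:::.glrlmCounts(lv, dirs[r, ], 4L)
        b <- glrlmBrute(lv, dirs[r, ], 4L)
        maxLen <- max(ncol(a), ncol(b))
        pad <- function(m) cbind(m, matrix(0L, nrow(m), maxLen - ncol(m)))
        expect_identical(pad(a), pad(b))
      }
      zm <- radphen:::.glszmCounts(lv, 4L)
      zb <- glszmBrute(lv)
      # compare zone multisets via the counts matrix
      bm <- matrix(0L, 4L, max(zb[, 2]))
      for (k in seq_len(nrow(zb))) bm[zb[k, 1], zb[k, 2]] <-
          bm[zb[k, 1], zb[k, 2]] + 1L
      maxS <- max(ncol(zm), ncol(bm))
      pad <- function(m) cbind(m, matrix(0L, nrow(m), maxS - ncol(m)))
      expect_identical(pad(zm), pad(bm))
    }
  })
})

test_that("GLCM matrices normalize to probability distributions", {
  withr::with_seed(3, {
    img <- array(rnorm(216), dim = c(6, 6, 6))
    vol <- volumeWithMask(img, array(runif(216) < 0.9, dim = c(6, 6, 6)))
    q <- discretizeVolume(vol, 6)
    dirs <- radphen:::.directions13()
    for (r in seq_len(nrow(dirs))) {
      cnt <- radphen:::.glcmCounts(q@levels, dirs[r, ], q@G)
      expect_true(all(cnt >= 0))
      P <- cnt / sum(cnt)
      expect_equal(sum(P), 1)
      expect_equal(P, t(P))  # symmetric accumulation
    }
  })
})

test_that("feature vectors are deterministic, translation-invariant and sized", {
  ph <- generatePhantom(c(20, 20, 20), radius = 4, texture = "checker",
                        noiseSd = 1, seed = 6)
  cfgSmall <- featureConfig(logSigmas = 1, waveletSubbands = "HHL")
  v1 <- extractFeatureVector(ph, cfgSmall)
  v2 <- extractFeatureVector(ph, cfgSmall)
  expect_identical(v1, v2)
  expect_true(all(is.finite(v1)))

  # translate image+mask by 2 voxels (even shift preserves Haar phase; the
  # mask margin exceeds the truncated LoG kernel, so boundary handling never
  # reaches in-mask voxels)
  big <- array(0, dim = c(24, 24, 24))
  bigMask <- array(FALSE, dim = c(24, 24, 24))
  big[3:22, 3:22, 3:22] <- ph@image[1:20, 1:20, 1:20]
  bigMask[3:22, 3:22, 3:22] <- ph@mask
  pad <- array(0, dim = c(24, 24, 24)); padMask <- array(FALSE, dim = c(24, 24, 24))
  pad[1:20, 1:20, 1:20] <- ph@image; padMask[1:20, 1:20, 1:20] <- ph@mask
  vPad <- extractFeatureVector(volumeWithMask(pad, padMask, ph@spacing),
                               cfgSmall)
  vShift <- extractFeatureVector(volumeWithMask(big, bigMask, ph@spacing),
                                 cfgSmall)
  expect_equal(vShift, vPad, tolerance = 1e-8)

  # bookkeeping: no filters -> first-order + shape + five texture families
  v0 <- extractFeatureVector(ph, featureConfig(logSigmas = numeric(0),
                                               waveletSubbands = character(0)))
  expect_length(v0, 15 + 6 + 5 * 5)
})

test_that("volumes round-trip through NIfTI with spacing preserved", {
  ph <- generatePhantom(c(10, 10, 10), radius = 3, spacing = c(0.7, 0.7, 1.2),
                        texture = "smooth-noise", seed = 12)
  ip <- tempfile(fileext = ".nii.gz"); mp <- tempfile(fileext = ".nii.gz")
  writeVolume(ph, ip, mp)
  back <- readVolume(ip, mp)
  expect_equal(back@image, ph@image, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back@mask, ph@mask, ignore_attr = TRUE)
  expect_equal(back@spacing, ph@spacing, tolerance = 1e-6)
})
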