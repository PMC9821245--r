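test_that("fixed-bin discretization maps the range onto 1..Ng", {
  roi <- intensityRoi(matrix(0:31, 4, 8), matrix(TRUE, 4, 8))
  d <- discretizeIntensities(roi, 32)
  expect_identical(sort(d$levelVec), 1:32)   # bijective on 0..31

  # constant ROI: min == max guard, everything level 1
  roiC <- intensityRoi(matrix(5, 3, 3), matrix(TRUE, 3, 3))
  expect_true(all(discretizeIntensities(roiC, 16)$levelVec == 1L))

  # shift and positive scaling leave levels unchanged
  roi2 <- intensityRoi(matrix(0:31 * 2.5 + 100, 4, 8), matrix(TRUE, 4, 8))
  expect_identical(discretizeIntensities(roi2, 32)$levelVec, d$levelVec)

  expect_error(discretizeIntensities(roi, 1), "nBins")
})

test_that("co-occurrence matrices match hand-enumerated pair sets", {
  # [[1,1],[2,2]] horizontal: both pairs equal-level -> diagonal mass
  roi <- intensityRoi(matrix(c(1, 2, 1, 2), 2, 2), matrix(TRUE, 2, 2))
  d <- discretizeIntensities(roi, 2)
  P <- glcmMatrix(d, c(0, 1, 0))
  expect_equal(unname(P), matrix(c(0.5, 0, 0, 0.5), 2, 2), ignore_attr = TRUE)

  # [[1,2],[1,2]] horizontal: all mass on (1,2)/(2,1)
  roi2 <- intensityRoi(matrix(c(1, 1, 2, 2), 2, 2), matrix(TRUE, 2, 2))
  d2 <- discretizeIntensities(roi2, 2)
  P2 <- glcmMatrix(d2, c(0, 1, 0))
  expect_equal(unname(P2), matrix(c(0, 0.5, 0.5, 0), 2, 2), ignore_attr = TRUE)
  f <- glcmFeatures(P2)
  expect_equal(f$difference_average, 1)
  expect_equal(f$contrast, 1)
  expect_equal(f$dissimilarity, 1)
  expect_equal(f$difference_variance, 0)

  # single masked voxel: no valid pair, flagged empty
  m1 <- matrix(FALSE, 2, 2); m1[1, 1] <- TRUE
  dOne <- discretizeIntensities(intensityRoi(matrix(1:4, 2, 2), m1), 2)
  expect_true(attr(glcmMatrix(dOne, c(0, 1, 0)), "empty"))

  # diagonal-only matrix: all difference features zero
  f0 <- glcmFeatures(glcmMatrix(d, c(0, 1, 0)))
  expect_equal(unname(unlist(f0)), c(0, 0, 0, 0))

  expect_error(glcmFeatures(matrix(1, 2, 2)), "normalized")
  expect_error(glcmMatrix(d, c(0, 2, 0)), "Chebyshev")
})

test_that("dissimilarity equals difference average on symmetric matrices", {
  set.seed(41)
  for (i in 1:25) {
    roi <- randomTinyRoi()
    d <- discretizeIntensities(roi, 4)
    for (mode in c("2Davg", "2Dmrg", "2DDmrg", "2Dvmrg", "3Davg", "3Dmrg")) {
      a <- glcmAggregate(d, "dissimilarity", mode)
      b <- glcmAggregate(d, "difference_average", mode)
      expect_equal(a, b, tolerance = 1e-12)
    }
  }
})

test_that("single-slice 2Dmrg equals 2Dvmrg and homogeneous stacks are flat", {
  set.seed(7)
  img <- matrix(rnorm(36), 6, 6)
  d <- discretizeIntensities(intensityRoi(img, matrix(TRUE, 6, 6)), 4)
  expect_equal(glcmAggregate(d, "contrast", "2Dmrg"),
               glcmAggregate(d, "contrast", "2Dvmrg"))

  dFlat <- discretizeIntensities(
    intensityRoi(array(1, c(5, 5, 3)), array(TRUE, c(5, 5, 3))), 8)
  for (mode in c("2Davg", "2Dmrg", "2DDmrg", "2Dvmrg", "3Davg", "3Dmrg"))
    expect_equal(glcmAggregate(dFlat, "contrast", mode), 0)
  expect_equal(ngtdmComplexity(dFlat, "2Dmrg"), 0)
  expect_equal(ngtdmComplexity(dFlat, "3D"), 0)
})

test_that("neighbourhood dependence energy handles degenerate cells", {
  # 2x2 single slice, all same level: every voxel has 3 equal neighbours
  d <- discretizeIntensities(
    intensityRoi(matrix(1, 2, 2), matrix(TRUE, 2, 2)), 4)
  expect_equal(ngldmDependenceCountEnergy(d), 1)

  # two equally occupied (level, dependence) cells -> energy 0.5
  m <- matrix(FALSE, 1, 4); m[1, 1:2] <- TRUE
  d2 <- discretizeIntensities(
    intensityRoi(matrix(c(0, 31, 0, 0), 1, 4), m), 32)
  # voxel A level 1 with 0 matching neighbours, voxel B level 32 with 0
  expect_equal(ngldmDependenceCountEnergy(d2), 0.5)
})

test_that("Geary's C matches its closed form and behaves as expected", {
  # two voxels with values 0 and 1: C = 1 exactly
  m <- array(FALSE, c(2, 2, 1)); m[1, 1, 1] <- m[2, 1, 1] <- TRUE
  img <- array(0, c(2, 2, 1)); img[2, 1, 1] <- 1
  expect_equal(gearysC(intensityRoi(img, m)), 1)

  # spatially random permutations average to ~1
  set.seed(5)
  base <- matrix(rnorm(49), 7, 7)
  cs <- replicate(40, {
    shuffled <- matrix(sample(base), 7, 7)
    gearysC(intensityRoi(shuffled, matrix(TRUE, 7, 7)))
  })
  expect_lt(abs(mean(cs) - 1), 0.05)

  # smooth gradient: strong positive spatial autocorrelation, C < 1
  grad <- matrix(rep(1:10, each = 10), 10, 10)
  expect_lt(gearysC(intensityRoi(grad, matrix(TRUE, 10, 10))), 1)

  # constant intensities: flagged missing
  expect_true(is.na(gearysC(intensityRoi(matrix(3, 4, 4),
                                         matrix(TRUE, 4, 4)))))
})

test_that("first-order features follow their decision rules", {
  m <- matrix(TRUE, 1, 4)
  roi <- intensityRoi(matrix(1:4, 1, 4), m)
  fo <- firstOrderFeatures(roi, nBins = 4)
  expect_equal(unname(fo["maximum"]), 4)
  expect_equal(unname(fo["range"]), 3)

  # level mode ties break to the lowest level
  roiT <- intensityRoi(matrix(c(0, 0, 31, 31), 1, 4), m)
  expect_equal(unname(firstOrderFeatures(roiT, nBins = 32)["mode"]), 1)

  # 10 equally spaced intensities: smallest g with frac(x >= g) <= 0.9 is 2
  roi10 <- intensityRoi(matrix(1:10, 1, 10), matrix(TRUE, 1, 10))
  expect_equal(
    unname(firstOrderFeatures(roi10, nBins = 4)["int_at_vol_fraction_90"]), 2)
})

test_that("extraction is deterministic, ordered, and mask-localized", {
  cohort <- smallCohort(2)
  roi <- discRoi(cohort[[1]])
  reg <- featureRegistry("fissure22")
  v1 <- extractFeatures(roi, reg)
  expect_length(v1, 22)
  expect_identical(names(v1), featureIds(reg))
  expect_true(all(is.finite(v1)))
  expect_identical(extractFeatures(roi, reg), v1)

  full <- featureRegistry("full")
  vf <- extractFeatures(roi, full)
  expect_length(vf, length(full))

  # voxels outside the mask never influence any feature
  set.seed(11)
  img2 <- roi@image
  img2[!roi@mask] <- rnorm(sum(!roi@mask), 500, 100)
  v2 <- extractFeatures(intensityRoi(img2, roi@mask, roi@spacing), reg)
  expect_equal(v2, v1)

  # adding a constant: level-based features invariant, maximum shifts
  v3 <- extractFeatures(intensityRoi(roi@image + 37, roi@mask, roi@spacing),
                        reg)
  lvlBased <- setdiff(featureIds(reg),
                      c("stat_maximum", "ivol_int_at_vol_fraction_90"))
  expect_equal(v3[lvlBased], v1[lvlBased], tolerance = 1e-8)
  expect_equal(unname(v3["stat_maximum"] - v1["stat_maximum"]), 37)
})
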