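# helpers to build AttentionMap objects directly, so the localization judge
# can be exercised independently of model training
mapFromColumns <- function(disc, hotCols) {
  dims <- dim(disc@roiMask)
  roiCols <- which(apply(disc@roiMask, 2, any))
  cs <- stats::setNames(rep(0, length(roiCols)), roiCols)
  cs[as.character(intersect(hotCols, roiCols))] <- 1
  overlay <- array(0, dims)
  hi <- array(FALSE, dims)
  for (cc in intersect(hotCols, roiCols)) {
    overlay[, cc, ][disc@roiMask[, cc, ]] <- 1
    hi[, cc, ] <- disc@roiMask[, cc, ]
  }
  new("AttentionMap", columnScores = cs, overlay = overlay,
      highlightedMask = hi, baselineScore = 0.9, mode = "drop")
}

test_that("occlusion replaces masked voxels and nothing else", {
  set.seed(83)
  d <- renderDisc(grade = 3, positions = "dorsal")
  roi <- discRoi(d)
  occ <- occludeColumns(roi, 70, occlusionConfig())
  expect_identical(occ@mask, roi@mask)
  changed <- which(occ@image != roi@image, arr.ind = TRUE)
  expect_true(all(changed[, 2] %in% 68:72))          # slab columns only
  expect_true(all(roi@mask[changed]))                # masked voxels only

  # slab over the fissure flattens it to about the ROI mean
  fisCols <- which(apply(d@fissureMask, 2, any))
  cc <- round(mean(fisCols))
  occF <- occludeColumns(roi, cc, occlusionConfig())
  slabFis <- d@fissureMask
  slabFis[, -((cc - 2):(cc + 2)), ] <- FALSE
  expect_lt(max(occF@image[slabFis]), mean(roi@image[roi@mask]) + 1e-9)

  # constant image with mean fill: occlusion is the identity
  roiC <- intensityRoi(array(7, c(10, 10, 2)), array(TRUE, c(10, 10, 2)))
  expect_equal(occludeColumns(roiC, 5, occlusionConfig())@image, roiC@image)

  # re-occluding at the same position with the original fill is idempotent
  fill <- mean(roi@image[roi@mask])
  once <- occludeColumns(roi, 70, occlusionConfig(), fillValue = fill)
  twice <- occludeColumns(once, 70, occlusionConfig(), fillValue = fill)
  expect_identical(once@image, twice@image)

  expect_error(occludeColumns(roi, 2, occlusionConfig(slabWidth = 1)),
               "slab")
})

test_that("attention maps cover exactly the ROI columns and flat maps stay empty", {
  set.seed(89)
  reg <- featureRegistry("fissure22")
  X <- matrix(rnorm(40 * 22), 40, 22, dimnames = list(NULL, featureIds(reg)))
  ens <- trainEnsemble(X, rep(0:1, 20), size = 2,
                       cfg = trainConfig(maxEpochs = 10))
  d <- renderDisc(grade = 3, positions = "dorsal")
  roi <- discRoi(d)
  map <- computeAttentionMap(roi, ens, reg)
  roiCols <- which(apply(roi@mask, 2, any))
  expect_length(map@columnScores, length(roiCols))
  expect_identical(as.integer(names(map@columnScores)), roiCols)
  expect_true(all(map@overlay[!roi@mask] == 0))
  expect_true(all(map@overlay >= 0 & map@overlay <= 1))

  # near-constant ROI: flat profile, empty highlight after the guard
  roiC <- intensityRoi(array(5, c(12, 16, 2)) , array(TRUE, c(12, 16, 2)))
  mapC <- suppressWarnings(computeAttentionMap(roiC, ens, reg))
  expect_true(all(abs(mapC@columnScores) < 1e-9))
  expect_false(any(mapC@highlightedMask))

  expect_error(computeAttentionMap(roi, ens, featureRegistry("full")),
               "registry")
})

test_that("drop-mode maps ignore global intensity shifts for shift-blind models", {
  set.seed(97)
  reg <- featureRegistry("fissure22")
  X <- matrix(rnorm(40 * 22), 40, 22, dimnames = list(NULL, featureIds(reg)))
  ens <- trainEnsemble(X, rep(0:1, 20), size = 2,
                       cfg = trainConfig(maxEpochs = 15))
  # silence the two features that are not shift-invariant (raw maximum and
  # intensity-at-volume-fraction); every other input works on discretized
  # levels or differences
  shiftSensitive <- match(c("stat_maximum", "ivol_int_at_vol_fraction_90"),
                          featureIds(reg))
  for (m in seq_along(ens@members))
    ens@members[[m]]$W1[shiftSensitive, ] <- 0
  d <- renderDisc(grade = 3, positions = "dorsal")
  roi <- discRoi(d)
  m1 <- computeAttentionMap(roi, ens, reg)
  roiShift <- intensityRoi(roi@image + 55, roi@mask, roi@spacing)
  m2 <- computeAttentionMap(roiShift, ens, reg)
  expect_equal(m1@columnScores, m2@columnScores, tolerance = 1e-7)
})

test_that("localization judging implements the correctness rules", {
  set.seed(101)
  dDor <- renderDisc(grade = 3, positions = "dorsal")
  fisCols <- which(apply(dDor@fissureMask, 2, any))

  # dorsal-peaked highlight on a dorsal disc: correct
  j1 <- judgeLocalization(mapFromColumns(dDor, fisCols[1:5]), dDor)
  expect_equal(j1$verdict, "correct")
  expect_equal(j1$matchedPositions, "dorsal")
  expect_equal(j1$failureMode, "none")

  # highlight far from the fissure: extension mismatch
  j2 <- judgeLocalization(mapFromColumns(dDor, c(20, 21, 22)), dDor)
  expect_equal(j2$verdict, "incorrect")
  expect_equal(j2$failureMode, "extension_mismatch")

  # ventral+dorsal truth with only the dorsal side highlighted
  dBoth <- renderDisc(grade = 3, positions = c("ventral", "dorsal"))
  fisB <- which(apply(dBoth@fissureMask, 2, any))
  roiCols <- which(apply(dBoth@roiMask, 2, any))
  dorsalOnly <- fisB[fisB > mean(range(roiCols))]
  j3 <- judgeLocalization(mapFromColumns(dBoth, dorsalOnly[1:5]), dBoth)
  expect_equal(j3$verdict, "incorrect")
  expect_equal(j3$failureMode, "missed_inferior_fissure")
  expect_equal(j3$matchedPositions, "dorsal")

  # both sides highlighted: correct, both matched
  ventralOnly <- fisB[fisB < mean(range(roiCols))]
  j4 <- judgeLocalization(
    mapFromColumns(dBoth, c(ventralOnly[1:4], dorsalOnly[1:4])), dBoth)
  expect_equal(j4$verdict, "correct")
  expect_setequal(j4$matchedPositions, c("ventral", "dorsal"))

  # lateral-only truth is always erroneous on midsagittal maps
  dLat <- renderDisc(grade = 3, positions = "lateral")
  j5 <- judgeLocalization(mapFromColumns(dLat, 40:45), dLat)
  expect_equal(j5$failureMode, "lateral_fissure")

  # upstream misclassification invalidates the map
  j6 <- judgeLocalization(NULL, renderDisc(grade = 3),
                          predictedPositive = TRUE)
  expect_equal(j6$failureMode, "misclassified")
  j7 <- judgeLocalization(NULL, dDor, predictedPositive = FALSE)
  expect_equal(j7$failureMode, "misclassified")

  # ineligible discs are rejected
  dDis <- renderDisc(grade = 4, positions = "dorsal", disrupted = TRUE)
  expect_error(judgeLocalization(mapFromColumns(dDor, fisCols), dDis),
               "eligible")
})

test_that("localization rates report integer percentages", {
  mk <- function(v) structure(list(verdict = v),
                              class = "LocalizationJudgement")
  js <- c(rep(list(mk("correct")), 90), rep(list(mk("incorrect")), 14))
  r <- localizationRate(js)
  expect_equal(r$nCorrect, 90)
  expect_equal(r$nTotal, 104)
  expect_equal(r$percent, 87)
  expect_equal(localizationRate(list(mk("correct")))$percent, 100)
  expect_equal(localizationRate(rep(list(mk("incorrect")), 5))$percent, 0)
  expect_error(localizationRate(list()), "judgement")
})
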